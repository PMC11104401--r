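{"schema":1,"task":"discounting","seed":123,"model":"softmax","subject_params":null}
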