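{"extraction_date":"2032-05-10"}
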