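# Default formal reaction-type vocabulary (editable configuration data).
activation
inhibition
catalysis
binding
transcription
translation
degradation
transport
synthesis
unknown
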