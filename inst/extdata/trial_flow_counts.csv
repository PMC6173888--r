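admitted,recruited,valid,completed_discharge,completed_followup
470,51,50,39,24
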