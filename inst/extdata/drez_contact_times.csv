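track_id,axon_entry_min,drez_contact_min
OPC1,0,255
OPC2,0,384
OPC3,0,214.8
OPC4,0,249.6
OPC5,0,174.6
OPC6,0,184.8
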