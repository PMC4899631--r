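region	start	end	frame_offset
FR1	0	78	0
CDR1	78	102	0
FR2	102	153	0
CDR2	153	177	0
FR3	177	294	0
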