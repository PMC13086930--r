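epitope_id	sequence	antigen	organism	category	cellular_location
EPI001	GRGSRVGVPSLKPTLGGKAV	pp150	CMV	pathogen	NA
EPI002	MAPKRLRLPHIRDDD	gpD	HSV2	pathogen	NA
EPI003	PKRLRLPHIRDD	gpD	HSV2	pathogen	NA
EPI004	SLKPTLGGK	pp150	CMV	pathogen	NA
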