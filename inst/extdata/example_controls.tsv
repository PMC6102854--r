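sg023	neg
sg024	neg
sg025	neg
sg026	neg
sg027	pos
sg028	pos
sg029	pos
sg030	pos
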