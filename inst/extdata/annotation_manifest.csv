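dataset,wsis,regions,tils
austin_crc,53,226,14385
cptac_coad,46,142,6214
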