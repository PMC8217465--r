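condition,answer,total,seizure_free,non_seizure_free
pet_complete,yes,10,4,6
pet_complete,no,4,1,3
flaws_complete,yes,6,1,5
flaws_complete,no,5,1,4
hfo_complete,yes,7,5,2
hfo_complete,no,8,0,8
multimodal,yes,6,5,1
multimodal,no,9,0,9
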