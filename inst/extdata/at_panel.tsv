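id	specificity
mal_1	malonyl
mal_2	malonyl
mal_3	malonyl
mal_4	malonyl
met_1	methylmalonyl
met_2	methylmalonyl
met_3	methylmalonyl
met_4	methylmalonyl
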