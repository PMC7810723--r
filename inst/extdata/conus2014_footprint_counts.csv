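measure,source,count,denominator
cover_any,imputed,1257,2858
cover_any,target,1250,2858
height_any,imputed,2449,2858
height_any,target,2440,2858
species_top2,imputed,2192,2858
cover_weighted,imputed,1391,2858
cover_weighted,target,1393,2858
height_weighted,imputed,2010,2858
height_weighted,target,2006,2858
plots_utilized,imputed,62758,67141
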