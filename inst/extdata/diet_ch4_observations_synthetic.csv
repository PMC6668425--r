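"species","d13c_diet","sd_diet","d13c_ch4","sd_ch4","year","source_id","provenance"
"cattle",-30,0.5,-69.604,4.2,1992,"synthetic_src1","reported"
"sheep",-29.5714,0.5,-75.7226,4.2,1997,"synthetic_src2","reported"
"goat",-29.1429,0.5,-70.8551,4.2,2001,"synthetic_src3","reported"
"steer",-28.7143,0.5,-66.5629,4.2,2004,"synthetic_src4","reported"
"cow",-28.2857,0.5,-71.9794,4.2,2008,"synthetic_src5","reported"
"buffalo",-27.8571,0.5,-69.0448,4.2,2012,"synthetic_src6","reported"
"cattle",-27.4286,0.5,-65.9546,4.2,1992,"synthetic_src1","reported"
"sheep",-27,0.5,-67.5115,4.2,1997,"synthetic_src2","reported"
"goat",-26.5714,0.5,-69.8171,4.2,2001,"synthetic_src3","reported"
"steer",-26.1429,0.5,-74.6088,4.2,2004,"synthetic_src4","reported"
"cow",-25.7143,0.5,-58.7741,4.2,2008,"synthetic_src5","reported"
"buffalo",-25.2857,0.5,-70.0537,4.2,2012,"synthetic_src6","reported"
"cattle",-24.8571,0.5,-67.1732,4.2,1992,"synthetic_src1","reported"
"sheep",-24.4286,0.5,-60.7518,4.2,1997,"synthetic_src2","reported"
"goat",-24,0.5,-62.7011,4.2,2001,"synthetic_src3","reported"
"steer",-23.5714,0.5,-56.1209,4.2,2004,"synthetic_src4","reported"
"cow",-23.1429,0.5,-58.2979,4.2,2008,"synthetic_src5","reported"
"buffalo",-22.7143,0.5,-71.0425,4.2,2012,"synthetic_src6","reported"
"cattle",-22.2857,0.5,-62.9723,4.2,1992,"synthetic_src1","reported"
"sheep",-21.8571,0.5,-66.524,4.2,1997,"synthetic_src2","reported"
"goat",-21.4286,0.5,-63.8603,4.2,2001,"synthetic_src3","reported"
"steer",-21,0.5,-59.8102,4.2,2004,"synthetic_src4","reported"
"cow",-20.5714,0.5,-64.0897,4.2,2008,"synthetic_src5","reported"
"buffalo",-20.1429,0.5,-62.2993,4.2,2012,"synthetic_src6","reported"
"cattle",-19.7143,0.5,-59.506,4.2,1992,"synthetic_src1","reported"
"sheep",-19.2857,0.5,-62.8589,4.2,1997,"synthetic_src2","reported"
"goat",-18.8571,0.5,-67.1533,4.2,2001,"synthetic_src3","reported"
"steer",-18.4286,0.5,-61.3626,4.2,2004,"synthetic_src4","composition"
"cow",-18,0.5,-63.573,4.2,2008,"synthetic_src5","composition"
"buffalo",-17.5714,0.5,-63.6303,4.2,2012,"synthetic_src6","composition"
"cattle",-17.1429,0.5,-52.771,4.2,1992,"synthetic_src1","composition"
"sheep",-16.7143,0.5,-57.8459,4.2,1997,"synthetic_src2","composition"
"goat",-16.2857,0.5,-59.938,4.2,2001,"synthetic_src3","composition"
"steer",-15.8571,0.5,-52.1211,4.2,2004,"synthetic_src4","composition"
"cow",-15.4286,0.5,-63.6674,4.2,2008,"synthetic_src5","composition"
"buffalo",-15,0.5,-58.6756,4.2,2012,"synthetic_src6","composition"
"cattle",-14.5714,0.5,-53.6371,4.2,1992,"synthetic_src1","composition"
"sheep",-14.1429,0.5,-51.5538,4.2,1997,"synthetic_src2","composition"
"goat",-13.7143,0.5,-53.8622,4.2,2001,"synthetic_src3","composition"
"steer",-13.2857,0.5,-55.9391,4.2,2004,"synthetic_src4","composition"
"cow",-12.8571,0.5,-49.0669,4.2,2008,"synthetic_src5","composition"
"buffalo",-12.4286,0.5,-58.3642,4.2,2012,"synthetic_src6","composition"
"cattle",-12,0.5,-60.1418,4.2,1992,"synthetic_src1","composition"
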