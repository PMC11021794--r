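>synthetic_cationic synthetic demo sequence (not a natural peptide)
MKLSRIAKTLVAGLLAVSCVQAKSFWDKVKGAAKKIGKTLAKNALTKLYCKITRKC
>synthetic_anionic synthetic demo sequence (not a natural peptide)
MADEESDLLEDFGSCEDDAYENSELACQLGDEWTPHSED
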