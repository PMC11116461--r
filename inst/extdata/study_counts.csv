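taxon,n_teeth_included,n_individuals
NEA,423,74
UPMH,444,102
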