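file	md5	provenance
photon_xs.tsv	f475f63515cf5784061d6d0cf90a1e45	generated: transcribed anchors + closed-form models
atomic_constants.csv	755be4db986235b2975c4b74b203cb5d	generated: transcribed atomic-data compilation
tissue_compositions.csv	2782fedc37578e8b18922900b81c43c2	generated: transcribed ICRP-style compositions
reference_anchors.csv	fba6f25bebcb9b8f03903497746aa229	generated: transcribed published reference values
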