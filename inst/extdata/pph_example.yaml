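# Example monophyly-constraint (PPH) configuration: a subset of widely
# accepted clades over the mitochondrial gene-order dataset, rooted on the
# sponge Tethya actinia.
root: Tethya_actinia
pphs:
  Brachiopoda: [Terebratalia_transversa, Terebratulina_retusa]
  Cephalopoda: [Nautilus_macromphalus, Loligo_bleekeri]
  Gastropoda: [Biomphalaria_glabrata, Cepaea_nemoralis, Albinaria_caerulea]
  Decapoda: [Eriocheir_sinensis, Pagurus_longicarpus, Cherax_destructor]
  Chelicerata: [Limulus_polyphemus, Steganacarus_magnus, Nymphon_gracile]
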