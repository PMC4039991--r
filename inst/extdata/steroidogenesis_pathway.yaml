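name: steroidogenesis
steps:
  - metabolite: cholesterol
    genes: [Hmgcr, Ldlr, Scarb1]
    any_of: true            # de novo synthesis or receptor-mediated uptake
  - metabolite: cholesterol_mito_outer
    genes: [Vdac1, Vdac2, Vdac3]
    any_of: true            # redundant voltage-dependent anion channels
  - metabolite: cholesterol_mito_inner
    genes: [Tspo, Star]
    any_of: false           # transduceosome core, both required
  - metabolite: pregnenolone
    genes: [Cyp11a1]
    any_of: false           # side-chain cleavage, rate-limiting entry
  - metabolite: downstream_steroids
    genes: [Cyp17a1, Hsd3b1]
    any_of: true            # either branch extends beyond pregnenolone
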