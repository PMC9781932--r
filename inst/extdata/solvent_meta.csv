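solvent_id,ei,notes
DMSO,11.7,EI dominated by photochemical oxidation potential
DMSO_adj,0.26,DMSO with photochemical oxidation contribution excluded
DMF,2.0,
4FM,0.51,almost green at the 0.5 cut
dioxane,0.8,
transcutol,0.7,
DMA,1.6,
water,0.0,reference aqueous component
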