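# provenance: figure-transcription (best-effort, schematic)
# Comparison mt gene arrangements for the synapomorphy screen and the
# ancestral reconstruction.  Limulus and the Argasidae-type row carry the
# ancestral arthropod arrangement (exact).  The Acariformes and derived
# Parasitiformes rows are schematic transcriptions built from the published
# verbal descriptions of those lineages (trnQ and trnY relocated, with
# positions varying among lineages; rrnS-trnV-rrnL inverted as a cluster in
# Sarcoptiformes but translocated without inversion in other Trombidiformes);
# they are best-effort stand-ins, not asserted gene-by-gene.
Limulus_polyphemus	cox1 trnL2 cox2 trnK trnD atp8 atp6 cox3 trnG nad3 trnA trnR trnN trnS1 trnE -trnF -nad5 -trnH -nad4 -nad4L trnT -trnP nad6 cob trnS2 -nad1 -trnL1 -rrnL -trnV -rrnS trnI -trnQ trnM nad2 trnW -trnC -trnY
Argasidae_sp	cox1 trnL2 cox2 trnK trnD atp8 atp6 cox3 trnG nad3 trnA trnR trnN trnS1 trnE -trnF -nad5 -trnH -nad4 -nad4L trnT -trnP nad6 cob trnS2 -nad1 -trnL1 -rrnL -trnV -rrnS trnI -trnQ trnM nad2 trnW -trnC -trnY
Ixodidae_sp	cox1 trnL2 cox2 trnK trnD atp8 atp6 cox3 trnG nad3 trnA trnR trnN trnS1 trnE trnL1 -trnF -nad5 -trnH -nad4 -nad4L trnT -trnP nad6 cob trnS2 -nad1 -rrnL -trnV -rrnS trnI -trnQ trnM nad2 trnW -trnC -trnY
Stylochyrus_rarior	cox1 trnL2 cox2 trnK trnD trnW atp8 atp6 cox3 trnG nad3 trnA trnR trnN trnS1 trnE -trnF -nad5 -trnH -nad4 -nad4L trnT -trnP nad6 cob trnS2 -nad1 -trnL1 -rrnL -trnV -rrnS trnI -trnQ trnM nad2 -trnC -trnY
Varroa_destructor	cox1 trnL2 cox2 trnD trnK atp8 atp6 cox3 trnG nad3 trnA trnR trnN trnS1 trnE -trnF -nad5 -trnH -nad4 -nad4L trnT -trnP nad6 cob trnS2 -nad1 -trnL1 -rrnL -trnV -rrnS trnI -trnQ -trnC -trnY trnM nad2 trnW
Demodex_sp	cox1 cox2 trnK trnD atp8 atp6 cox3 trnG nad3 trnQ trnA trnR trnN trnS1 trnE -trnF -nad5 -trnH -nad4 -nad4L trnT -trnP -rrnL -trnV -rrnS nad6 cob trnS2 -trnY -nad1 -trnL2 -trnL1 trnI trnM nad2 trnW -trnC
Tetranychus_urticae	cox1 trnT cox2 trnK trnD atp8 atp6 cox3 nad3 trnG trnY -nad1 -trnQ -rrnL -trnC -trnV -rrnS -trnL1 trnA trnR trnN trnE -trnF -nad5 -trnH -nad4 -nad4L -trnP nad6 cob trnS2 trnL2 trnI trnM nad2 trnW trnS1
Leptotrombidium_pallidum	cox1 cox2 trnD atp8 atp6 -trnQ cox3 trnG nad3 trnA trnR trnN trnS1 trnE -trnY -trnF -nad5 -trnH -nad4 -nad4L -trnP trnT nad6 cob trnS2 -nad1 -trnL1 -trnL2 -rrnL -trnV -rrnS trnI trnK trnM nad2 trnW -trnC
Unionicola_parkeri	cox1 trnL2 cox2 trnK trnD atp8 atp6 cox3 trnY trnG nad3 trnA trnR trnN trnS1 trnE -trnF -nad5 -trnH -nad4 -nad4L trnT -trnP nad6 cob trnS2 -nad1 -trnL1 -rrnL -trnV -rrnS trnI trnM trnQ nad2 trnW -trnC
Dermatophagoides_sp	cox1 cox2 trnK trnD atp8 atp6 cox3 trnG nad3 trnA trnR trnN trnS1 trnE -trnF -nad5 -trnH -nad4 -nad4L trnT -trnP nad6 cob trnS2 -nad1 -trnL1 -trnL2 rrnS trnV rrnL trnI -trnQ trnM nad2 trnW -trnC -trnY
Steganacarus_magnus	cox1 cox2 trnK trnD atp8 atp6 cox3 trnG nad3 trnA trnR trnN trnS1 trnE -trnF -nad5 -trnH -nad4 -nad4L trnT -trnP nad6 cob trnS2 -nad1 -trnL1 rrnS trnV rrnL -trnL2 trnI trnM -trnQ nad2 trnW -trnC -trnY
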