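# Hypothetical ancestral mt gene arrangement of arthropods (Limulus-type),
# linearized at cox1; leading '-' marks N-strand genes; CR between rrnS and trnI.
# Exchange format: taxon<TAB>gene list in reading order.
Hypothetical_arthropod_ancestor	cox1 trnL2 cox2 trnK trnD atp8 atp6 cox3 trnG nad3 trnA trnR trnN trnS1 trnE -trnF -nad5 -trnH -nad4 -nad4L trnT -trnP nad6 cob trnS2 -nad1 -trnL1 -rrnL -trnV -rrnS CR trnI -trnQ trnM nad2 trnW -trnC -trnY
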