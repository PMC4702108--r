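(Limulus_polyphemus,(((Argasidae_sp,Ixodidae_sp),(Stylochyrus_rarior,Varroa_destructor)),((Phyllocoptes_taishanensis,Epitrimerus_sabinae),((Tetranychus_urticae,(Demodex_sp,(Leptotrombidium_pallidum,Unionicola_parkeri))),(Dermatophagoides_sp,Steganacarus_magnus)))));
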