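species,wing_span,voltinism,overwintering,diet
Aglais_urticae,50.5,2.1,adult,monophagous
Pieris_napi,44.0,2.4,pupae,broad oligophagous
Maniola_jurtina,51.0,1.0,larvae,broad oligophagous
Polyommatus_icarus,31.5,2.2,larvae,broad oligophagous
Gonepteryx_rhamni,55.5,1.0,adult,broad oligophagous
Papilio_machaon,76.0,1.8,pupae,broad oligophagous
Thymelicus_sylvestris,27.5,1.0,egg,polyphagous
Vanessa_atalanta,58.5,2.0,adult,monophagous
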