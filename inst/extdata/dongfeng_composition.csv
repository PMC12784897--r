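order,family,species,occurrence_pct,abundance_pct,biomass_pct,iri_reported
Cypriniformes,Xenocyprididae,Opsariichthys bidens,88.89,2.80,2.43,464.75
Cypriniformes,Xenocyprididae,Hemiculter leucisculus,100,6.01,2.63,863.69
Cypriniformes,Xenocyprididae,Culter alburnus,11.11,0.08,0.10,2.01
Cypriniformes,Xenocyprididae,Hypophthalmichthys molitrix,11.11,0.08,9.48,106.27
Cypriniformes,Gobionidae,Pseudorasbora parva,55.56,0.58,0.05,34.84
Cypriniformes,Gobionidae,Abbottina rivularis,22.22,0.16,0.02,4.01
Cypriniformes,Acheilognathidae,Rhodeus sinensis,66.67,3.21,0.27,231.82
Cypriniformes,Acheilognathidae,Rhodeus ocellatus,11.11,0.49,0.08,6.36
Cypriniformes,Cyprinidae,Spinibarbus sinensis,22.22,0.49,9.20,215.35
Cypriniformes,Cyprinidae,Onychostoma yunnanense,11.11,0.08,0.22,3.34
Cypriniformes,Cyprinidae,Onychostoma simum,22.22,0.33,0.27,13.24
Cypriniformes,Cyprinidae,Cyprinus carpio,77.78,1.07,1.09,168.02
Cypriniformes,Cyprinidae,Carassius auratus,100,22.55,14.69,3724.24
Cypriniformes,Cyprinidae,Pseudogyrinocheilus prochilus,55.56,4.77,8.22,721.86
Cypriniformes,Cyprinidae,Discogobio yunnanensis,33.33,0.25,0.06,10.14
Cypriniformes,Cobitidae,Misgurnus dabryanus,11.11,0.33,0.08,4.60
Siluriformes,Siluridae,Silurus asotus,44.44,0.33,3.77,182.36
Siluriformes,Siluridae,Silurus meridionalis,11.11,0.08,0.07,1.65
Siluriformes,Bagridae,Tachysurus sinensis,33.33,1.07,0.94,67.05
Siluriformes,Bagridae,Tachysurus crassilabris,55.56,1.81,1.40,178.35
Gobiiformes,Gobiidae,Rhinogobius similis,66.67,1.15,0.03,78.83
Cichliformes,Cichlidae,Coptodon zillii,100,19.34,17.77,3711.27
Centrarchiformes,Centrarchidae,Lepomis cyanellus,100,32.92,27.14,6006.23
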