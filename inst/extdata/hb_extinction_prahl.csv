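# Molar extinction coefficients of human oxy- and deoxyhemoglobin (cm^-1 / M),
# transcribed (rounded) from the standard Prahl/van Assendelft compilation.
# source_id: prahl-omlc-hemoglobin (transcribed subset, 650-900 nm)
wavelength_nm,eps_hbo2,eps_hb
650,368.0,3750.1
660,319.6,3226.6
680,277.6,2407.9
700,290.0,1794.3
720,348.0,1244.0
730,390.0,1102.2
740,446.0,1115.9
750,518.0,1405.2
760,586.0,1548.5
780,710.0,1075.4
800,816.0,761.7
820,916.0,693.8
840,1022.0,692.4
850,1058.0,691.3
860,1096.0,692.4
880,1154.0,726.4
900,1198.0,761.8
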