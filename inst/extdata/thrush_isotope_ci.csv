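species,source,lower,upper
T_amaurochalinus,omnivorous,0,0.12
T_amaurochalinus,predators,0.18,0.45
T_amaurochalinus,herbivorous,0,0.16
T_amaurochalinus,surface_detritivorous,0,0.15
T_amaurochalinus,terrestrial_detritivorous,0,0.11
T_amaurochalinus,c4cam_fruits,0,0.03
T_amaurochalinus,c3_fruits,0.36,0.57
T_albicollis,omnivorous,0,0.23
T_albicollis,predators,0.05,0.38
T_albicollis,herbivorous,0,0.33
T_albicollis,surface_detritivorous,0,0.3
T_albicollis,terrestrial_detritivorous,0,0.22
T_albicollis,c4cam_fruits,0,0.06
T_albicollis,c3_fruits,0.12,0.46
T_rufiventris,omnivorous,0,0.05
T_rufiventris,predators,0.55,0.69
T_rufiventris,herbivorous,0,0.06
T_rufiventris,surface_detritivorous,0,0.07
T_rufiventris,terrestrial_detritivorous,0,0.06
T_rufiventris,c4cam_fruits,0,0
T_rufiventris,c3_fruits,0.21,0.37
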