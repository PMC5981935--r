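scenario,admin_other_details,admin_fit_note,gp_no_action,gp_prescription,other_appointment,gp_phone_back,gp_appointment,declared_admin_share,declared_recall_share
base,0.12,0.15,0.10,0.20,0.13,0.15,0.15,0.27,0.43
scenario_1,0.15,0.25,0.10,0.20,0.10,0.10,0.10,0.40,0.30
scenario_2,0.15,0.20,0.20,0.20,0.10,0.10,0.05,0.35,0.25
scenario_3,0.10,0.20,0.30,0.20,0.05,0.10,0.05,0.30,0.20
scenario_4,0.05,0.15,0.40,0.25,0.05,0.05,0.05,0.20,0.15
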