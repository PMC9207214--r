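animal_id,group,responded
intact_01,intact,1
intact_02,intact,1
intact_03,intact,1
intact_04,intact,1
intact_05,intact,1
intact_06,intact,1
intact_07,intact,1
intact_08,intact,0
ablctrl_01,ablation_control,1
ablctrl_02,ablation_control,1
ablctrl_03,ablation_control,1
ablctrl_04,ablation_control,1
ablctrl_05,ablation_control,1
ablctrl_06,ablation_control,1
ablctrl_07,ablation_control,1
ablctrl_08,ablation_control,1
ablated_01,sensory_olc_ablated,1
ablated_02,sensory_olc_ablated,1
ablated_03,sensory_olc_ablated,1
ablated_04,sensory_olc_ablated,1
ablated_05,sensory_olc_ablated,1
ablated_06,sensory_olc_ablated,1
ablated_07,sensory_olc_ablated,1
ablated_08,sensory_olc_ablated,1
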