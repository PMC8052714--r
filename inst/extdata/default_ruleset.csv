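"type_id","modulator_domain","source_domain","target_domain","same_cell","notes"
"cyt_mod_cell_src_cyt_tgt","cytokine","cell","cytokine","none","cytokine modulates a cell that stimulates/suppresses a cytokine"
"cell_mod_cell_src_cyt_tgt","cell","cell","cytokine","none","cell modulates a cell acting on a cytokine target; the two cells may differ"
"cyt_mod_cell_autocrine","cytokine","cell","cell","source_target_same","cytokine modulates a cell acting on itself (autocrine)"
"cell_mod_cyt_src_same_cell","cell","cytokine","cell","all_cell_roles_same","cell modulates a cytokine that acts back on the same cell"
"linear_cyt_to_cell","none","cytokine","cell","none","non-modulated cytokine acting on a cell"
"linear_cell_to_any","none","cell","any","none","non-modulated cell acting on any biomarker"
"cell_self_unit_mod","cell_or_ext","cell","cell","all_cell_roles_same","cell self-relationship modulated by the same cell or by non-biomarker factors (ext)"
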