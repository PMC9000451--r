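{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "enzybind study report",
  "type": "object",
  "required": ["ic50_table", "kinetic_table", "quench_table",
               "thermo_table", "consistency_flags", "parameters"],
  "properties": {
    "ic50_table": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["sample", "ic50_mg_ml", "ci95_low_mg_ml",
                     "ci95_high_mg_ml", "probit_slope", "r2"]
      }
    },
    "kinetic_table": {
      "type": "object",
      "required": ["Vmax_per_min", "Km_mg_ml", "Ki_mg_ml",
                   "Km_app_by_I_mg_ml", "verdict"]
    },
    "quench_table": {
      "type": "object",
      "required": ["by_T", "mechanism"]
    },
    "thermo_table": {
      "type": "object"
    },
    "consistency_flags": {
      "type": "array",
      "items": {"type": "string"}
    },
    "parameters": {
      "type": "object",
      "required": ["tau0_s", "vmax_tol", "intercept_tol",
                   "clamp_margin_pct", "force_tol_dH_kJ_mol",
                   "force_tol_dS_J_mol_K", "consistency_tol_kJ_mol"]
    }
  }
}
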