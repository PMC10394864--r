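{
  "title": "tlroadmap roadmap report",
  "description": "Required blocks and field types of report.json; every number in a report is reproducible from (config, seed, input file) alone.",
  "required": {
    "config": {
      "required": {
        "scale": "string",
        "level": "number",
        "v_folds": "integer",
        "seed": "integer"
      }
    },
    "cohort": {
      "required": {
        "n": "integer",
        "events": "integer",
        "treated": "integer",
        "control": "integer",
        "covariates": "array"
      }
    },
    "diagnostics": {
      "required": {
        "positivity_tables": "object",
        "positivity_flags": "array",
        "ps_cstat": "number",
        "ps_overlap": "object"
      }
    },
    "estimation": {
      "required": {
        "scale": "string",
        "psi1": "number",
        "psi0": "number",
        "estimate": "number",
        "se": "number",
        "ci": "number",
        "epsilon": "number",
        "ps_bound": "number",
        "mean_ic": "number",
        "sl_outcome": "object",
        "sl_ps": "object"
      }
    },
    "sensitivity": {
      "required": {
        "grid": "array",
        "g_value": "number",
        "flip": "object"
      }
    },
    "seed": "integer",
    "versions": "object"
  }
}
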