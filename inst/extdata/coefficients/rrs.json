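{
  "models": [
    {
      "model_id": "rrs_women",
      "sex": "female",
      "baseline_survival": 0.98634,
      "mean_linear_predictor": 22.325,
      "terms": [
        {"label": "age", "beta": 0.0799, "factors": [{"field": "age", "transform": "identity"}]},
        {"label": "ln_systolic_bp", "beta": 3.137, "factors": [{"field": "systolic_bp", "transform": "log"}]},
        {"label": "ln_hscrp", "beta": 0.18, "factors": [{"field": "hscrp", "transform": "log"}]},
        {"label": "ln_total_cholesterol", "beta": 1.382, "factors": [{"field": "total_cholesterol", "transform": "log"}]},
        {"label": "ln_hdl_cholesterol", "beta": -1.172, "factors": [{"field": "hdl_cholesterol", "transform": "log"}]},
        {"label": "hba1c_if_diabetic", "beta": 0.134, "condition": "diabetic", "factors": [{"field": "hba1c", "transform": "identity"}]},
        {"label": "smoker", "beta": 0.818, "condition": "current_smoker", "factors": []},
        {"label": "family_history", "beta": 0.438, "condition": "family_history", "factors": []}
      ]
    },
    {
      "model_id": "rrs_men",
      "sex": "male",
      "baseline_survival": 0.899,
      "mean_linear_predictor": 33.097,
      "terms": [
        {"label": "ln_age", "beta": 4.385, "factors": [{"field": "age", "transform": "log"}]},
        {"label": "ln_systolic_bp", "beta": 2.607, "factors": [{"field": "systolic_bp", "transform": "log"}]},
        {"label": "ln_total_cholesterol", "beta": 0.963, "factors": [{"field": "total_cholesterol", "transform": "log"}]},
        {"label": "ln_hdl_cholesterol", "beta": -0.772, "factors": [{"field": "hdl_cholesterol", "transform": "log"}]},
        {"label": "ln_hscrp", "beta": 0.102, "factors": [{"field": "hscrp", "transform": "log"}]},
        {"label": "smoker", "beta": 0.405, "condition": "current_smoker", "factors": []},
        {"label": "family_history", "beta": 0.541, "condition": "family_history", "factors": []}
      ]
    }
  ]
}
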