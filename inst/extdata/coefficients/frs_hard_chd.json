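{
  "models": [
    {
      "model_id": "frs_hard_chd_women",
      "sex": "female",
      "baseline_survival": 0.98767,
      "mean_linear_predictor": 146.5933061,
      "terms": [
        {"label": "ln_age", "beta": 31.764001, "factors": [{"field": "age", "transform": "log"}]},
        {"label": "ln_total_cholesterol", "beta": 22.465206, "factors": [{"field": "total_cholesterol", "transform": "log"}]},
        {"label": "ln_hdl_cholesterol", "beta": -1.187731, "factors": [{"field": "hdl_cholesterol", "transform": "log"}]},
        {"label": "ln_systolic_bp", "beta": 2.552905, "factors": [{"field": "systolic_bp", "transform": "log"}]},
        {"label": "bp_treated", "beta": 0.420251, "condition": "bp_medication", "factors": []},
        {"label": "smoker", "beta": 13.07543, "condition": "current_smoker", "factors": []},
        {"label": "ln_age_x_ln_total_cholesterol", "beta": -5.060998, "factors": [{"field": "age", "transform": "log"}, {"field": "total_cholesterol", "transform": "log"}]},
        {"label": "ln_age_x_smoker", "beta": -2.996945, "condition": "current_smoker", "factors": [{"field": "age", "transform": "log", "cap": 78}]}
      ]
    },
    {
      "model_id": "frs_hard_chd_men",
      "sex": "male",
      "baseline_survival": 0.9402,
      "mean_linear_predictor": 172.300168,
      "terms": [
        {"label": "ln_age", "beta": 52.00961, "factors": [{"field": "age", "transform": "log"}]},
        {"label": "ln_total_cholesterol", "beta": 20.014077, "factors": [{"field": "total_cholesterol", "transform": "log"}]},
        {"label": "ln_hdl_cholesterol", "beta": -0.905964, "factors": [{"field": "hdl_cholesterol", "transform": "log"}]},
        {"label": "ln_systolic_bp", "beta": 1.305784, "factors": [{"field": "systolic_bp", "transform": "log"}]},
        {"label": "bp_treated", "beta": 0.241549, "condition": "bp_medication", "factors": []},
        {"label": "smoker", "beta": 12.096316, "condition": "current_smoker", "factors": []},
        {"label": "ln_age_x_ln_total_cholesterol", "beta": -4.605038, "factors": [{"field": "age", "transform": "log"}, {"field": "total_cholesterol", "transform": "log"}]},
        {"label": "ln_age_x_smoker", "beta": -2.84367, "condition": "current_smoker", "factors": [{"field": "age", "transform": "log", "cap": 70}]},
        {"label": "ln_age_squared", "beta": -2.93323, "factors": [{"field": "age", "transform": "log"}, {"field": "age", "transform": "log"}]}
      ]
    }
  ]
}
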