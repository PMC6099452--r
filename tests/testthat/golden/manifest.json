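{
  "package": "rxlines",
  "version": "0.1.0",
  "seed": 20180605,
  "config": {
    "prescriptions": "prescriptions.csv",
    "clinical": "clinical.csv",
    "demographics": "demographics.csv",
    "pca": "pca.csv",
    "cpi": "cpi.csv",
    "population": "population.csv",
    "prevalence": "prevalence.csv",
    "prescribing": "prescribing.csv",
    "practice_meta": "practice_meta.csv",
    "class_map_path": "drug_class_map.csv",
    "gap_days": 183,
    "cpi_base_year": 2016,
    "window_months": 12,
    "min_practices_per_month": 10,
    "combination_mode_patient": "patient_level",
    "combination_mode_aggregated": "aggregated",
    "percentile_method": "linear interpolation (type 7)",
    "kurtosis": "excess (moment formula)"
  },
  "stages": {
    "cohort": {
      "rows_in": 150,
      "rows_kept": 132,
      "rows_filtered": 18,
      "rows_rejected": 0,
      "excluded_by_reason": {
        "age_at_dx_lt_35": 7,
        "insulin_within_12m": 5,
        "no_diabetes_evidence": 2,
        "pcos_code": 4
      }
    },
    "lines": {
      "rows_in": 247,
      "rows_kept": 247,
      "rows_filtered": 0,
      "rows_rejected": 0
    },
    "trends": {
      "rows_in": 247,
      "rows_kept": 247,
      "rows_filtered": 0,
      "rows_rejected": 0,
      "prevalence_fit_r2": 1
    },
    "geo": {
      "rows_in": 6120,
      "rows_kept": 5271,
      "rows_filtered": 849,
      "rows_rejected": 0
    }
  },
  "outputs": {
    "cohort.csv": 150,
    "lines.csv": 247,
    "line_shares.csv": 114,
    "episodes.csv": 278,
    "national_trends.csv": 120,
    "ccg_summary.csv": 10,
    "decile_series.csv": 756,
    "savings.json": 1
  }
}
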