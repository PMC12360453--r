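.datatable.aware <- TRUE

utils::globalVariables(c(
  ".", ".N", ".SD", "count", "enrollees", "year", "doy", "base_lp", "lag",
  "week_id", "g", "date", "zip", "stratum_id", "arm", "start_date",
  "end_date", "year_frac", "cause", "admission_type", "person_days"
))
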