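{
  "title": "timscreen evaluation report",
  "description": "Structural schema for the JSON written by write_evaluation_report(): required top-level fields and their types; optional fields (rt_window_sensitivity, trendlines, confusion) may be null or absent.",
  "required": {
    "n_library_ions": "number",
    "category_counts": "object",
    "spectral_coverage_pct": "number"
  },
  "optional": {
    "score_summary": "object",
    "rt_window_sensitivity": "object",
    "trendlines": "object",
    "confusion": "object"
  }
}
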