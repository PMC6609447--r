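# Generated by data-raw/make-reference-tables.R; do not edit by hand.
.reference_checksums <- c(
  "synthetic-s-cone-opic.csv" = "ef62fca0bf93b7c5b31027f3641caa09",
  "synthetic-m-cone-opic.csv" = "ec0afc124c5e802837b2a8a9db00e928",
  "synthetic-l-cone-opic.csv" = "8837891b11830c4fd2dc4c3efd4a5596",
  "synthetic-rhodopic.csv" = "cbc00ef0316fa18a0a25b016458cd028",
  "synthetic-melanopic.csv" = "a5db8c97bfc2bb3807efa2dce8f7717d",
  "synthetic-photopic-v.csv" = "d8dae5ffee28baf43a9aafddbf9b15f1",
  "synthetic-blue-light-hazard.csv" = "330b0b92cdc9fb76e1adc31b343706a4"
)
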