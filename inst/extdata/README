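nepc_panel_bins.tsv
  Detection-bin symbols for the 15-chimera NEPC panel across six public
  RNA-seq datasets (GEO series GSE156289, GSE154575, GSE118206, GSE31528),
  transcribed from the published detection table accompanying the panel.
  Bin scale over mean junction-spanning read counts x:
    -    x < 1
    +    1 <= x < 5
    ++   5 <= x < 10
    +++  x >= 10
  Version 1 of the transcription; columns are dataset labels, rows are the
  panel chimeras in published order.
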