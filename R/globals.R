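# data.table non-standard evaluation symbols
utils::globalVariables(c(
  "read_id", "species", "gene", "start", "strand", "haplotype",
  "query_id", "subject_id", "evalue", "code", "word", "target", "diag_nt",
  "score", "target_id", "r_start", "t_start", "t_end", "n_targets", "bases",
  "pos", "base", "N", "count", "gene_id", "position", "group1_base",
  "group2_base", "category", "dominant", "read", "seq_idx", "aa_start",
  "frame", "r_nt", "t_nt", "best", "mate", "base_id", "matches", "mismatches",
  "q_size", "t_size", "i.t_nt", "i.seq_idx", "i.aa_start"
))
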