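#' @import data.table
NULL

.datatable.aware <- TRUE

# quiet R CMD check about data.table non-standard evaluation symbols
utils::globalVariables(c(
  ".", ".N", ".SD", "allele", "apos", "astart", "base", "best", "c_a",
  "c_b", "c_count", "c_obs", "chi2_p", "cons_parent1", "cons_parent2",
  "context", "count", "count_p1", "count_p2", "cpg", "end", "grp", "idx",
  "lev_a", "lev_b", "length", "level", "line", "margin", "meth_a",
  "meth_b", "mismatches", "n_alleles", "n_lines", "n_meth_a", "n_meth_b",
  "n_sites", "nbest", "nxt", "ok_parent1", "ok_parent2", "parent", "pos",
  "pos0", "prv", "qok", "read", "ref", "sc_a", "sc_b", "scaffold",
  "sense", "snp_base", "snp_off", "spos", "st_a", "st_b", "start",
  "strand", "subject", "t_a", "t_b", "t_count", "t_obs", "win",
  "win_allele", "x.spos"))
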