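#' @keywords internal
#' @import data.table
"_PACKAGE"

# columns used in data.table non-standard evaluation
utils::globalVariables(c(
  "SNP", "CHR", "BP", "A1", "A2", "BETA", "SE", "Z", "P", "N",
  "BETA1", "SE1", "Z1", "P1", "N1", "BETA2", "SE2", "Z2", "P2", "N2",
  "gene_id", "tissue", "variant_id", "b_eqtl", "se_eqtl", "z_eqtl",
  "p_eqtl", "p_smr", "p_heidi", "b_xy", "heidi_status", "method_count",
  "start", "end", "lead_snp", "lead_p", "n_members", "category",
  "drug_name", "moa", "indication", "sign", "source", "net_direction",
  "predicted_moa", "n_up", "n_down", "n_matched", "v", "set", "set_p",
  "grp", "smr_significant", "smr_nominal"
))
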