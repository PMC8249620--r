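# Shared model fixtures, built in code.

toy_signal <- function() signal_params(r1 = 9.01e-4, r2 = 3.05e-4)

# 3-state gene with modest copy numbers (means ~1-30): cheap FSP spaces
toy_gene_3s <- function(mode = c("enhance", "suppress")) {
  mode <- match.arg(mode)
  if (mode == "enhance") {
    top <- gene_topology(3, "01", "enhance")
    rates <- gene_rates(top,
      k = c("01" = 1e-3, "10" = 1e-2, "12" = 4e-3, "21" = 4e-3),
      b = 2e-2, alpha = c(1e-4, 0.02, 0.04), delta = 2e-4)
    gene_model(top, rates, inhibitor_map(b_mg132 = 6e-3, k01_u0126 = 3e-4))
  } else {
    top <- gene_topology(3, "10", "suppress")
    rates <- gene_rates(top,
      k = c("01" = 1e-3, "10" = 1e-2, "12" = 4e-3, "21" = 4e-3),
      b = 5, alpha = c(1e-4, 0.02, 0.04), delta = 2e-4)
    gene_model(top, rates, inhibitor_map(b_mg132 = 0.5, k01_u0126 = 3e-4))
  }
}

constitutive_gene <- function(alpha = 1e-2, delta = 1e-4) {
  top <- gene_topology(1)
  gene_model(top, gene_rates(top, alpha = alpha, delta = delta))
}

toy_model <- function() {
  combinatorial_model("toy", toy_signal(),
    list(g1 = toy_gene_3s("enhance"), g2 = toy_gene_3s("suppress")))
}

# CM1 with transcription rates scaled down 10x (copy numbers ~10x smaller,
# switching dynamics untouched): same mechanisms at tractable state-space
# sizes for simulation-heavy tests
cm1_scaled <- function(scale = 0.1) {
  m <- cm_model("CM1")
  for (g in names(m$genes)) {
    m$genes[[g]]$rates$alpha <- m$genes[[g]]$rates$alpha * scale
  }
  m$name <- "CM1s"
  m
}

design_times <- function() c(0, 1800, 3600, 7200, 14400)
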