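# Regenerates inst/extdata/dip_null_quantiles.csv: quantiles of the dip
# statistic under the uniform (unimodal) null, 50,000 Monte-Carlo replicates
# per tabulated sample size.  Run from the package root:
#   Rscript tools/make_dip_table.R
Rcpp::sourceCpp("src/dip.cpp")

ns <- c(30, 40, 50, 65, 80, 100, 130, 160, 200, 250, 300, 400, 500,
        700, 1000, 1500, 2000)
probs <- c(0.01, 0.02, 0.05, 0.10, 0.20, 0.30, 0.40, 0.50, 0.60, 0.70,
           0.80, 0.90, 0.95, 0.975, 0.99, 0.995, 0.999)
B <- 50000

set.seed(20260909)
tab <- t(vapply(ns, function(n) {
  q <- quantile(dip_null_cpp(n, B), probs, type = 7)
  message("n = ", n)
  q
}, numeric(length(probs))))

out <- data.frame(n = ns, tab, check.names = FALSE)
colnames(out) <- c("n", format(probs, trim = TRUE))
dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
write.csv(out, "inst/extdata/dip_null_quantiles.csv", row.names = FALSE,
          quote = FALSE)
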