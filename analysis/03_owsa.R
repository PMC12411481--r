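#!/usr/bin/env Rscript
# One-way deterministic sensitivity analysis (tornado) on every published
# parameter range, CPS>=10 base case.

library(tnbcCEA)

dir.create("results", showWarnings = FALSE)
config <- cps10_config()
tor <- owsa(config)
cat(sprintf("base-case ICER: $%.0f/QALY\n", attr(tor, "base_icer")))
cat("widest bars:\n")
print(head(tor, 5))

write.csv(tor, "results/tornado.csv", row.names = FALSE)
if (requireNamespace("ggplot2", quietly = TRUE)) {
  ggplot2::ggsave("results/tornado.pdf", plot_tornado(tor),
                  width = 7, height = 5)
}
cat("written: results/tornado.csv\n")
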