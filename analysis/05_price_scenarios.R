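#!/usr/bin/env Rscript
# Price-discount scenarios: rerun the CPS>=10 model with the pembrolizumab
# unit price reduced by 0-95%.

library(tnbcCEA)

dir.create("results", showWarnings = FALSE)
config <- cps10_config()
wtp <- config$settings$wtp

rows <- lapply(c(0, 0.5, 0.8, 0.9, 0.95), function(d) {
  res <- run_cea(apply_price_discount(config, "pembrolizumab", d))
  data.frame(discount = d,
             incremental_cost = res$incremental$delta_cost,
             incremental_qaly = res$incremental$delta_qaly,
             icer = res$incremental$icer,
             cost_effective = res$incremental$icer < wtp)
})
tab <- do.call(rbind, rows)
print(tab, row.names = FALSE)
cat(sprintf("\nat an 80%% price cut the ICER is $%.0f/QALY vs WTP $%s\n",
            tab$icer[tab$discount == 0.8], format(wtp, big.mark = ",")))
write.csv(tab, "results/price_scenarios.csv", row.names = FALSE)
cat("written: results/price_scenarios.csv\n")
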