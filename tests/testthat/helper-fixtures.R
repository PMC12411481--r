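# Table-1 fitted curves for the CPS>=10 subgroup, used across tests
table1_curves <- function() {
  list(
    pem_pfs = surv_model("lognormal", meanlog = 2.3487, sdlog = 1.2258),
    pem_os  = surv_model("lognormal", meanlog = 3.1454, sdlog = 1.1058),
    plc_pfs = surv_model("loglogistic", shape = 1.763, scale = 6.618),
    plc_os  = surv_model("loglogistic", shape = 1.702, scale = 16.631)
  )
}

base_config <- local({
  cfg <- NULL
  function() {
    if (is.null(cfg)) cfg <<- cps10_config()
    cfg
  }
})

# small flat-survival helper: everyone alive until `drop_at`, then constant s
step_curve <- function(drop_at, s) {
  function(t) ifelse(t < drop_at, 1, s)
}
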