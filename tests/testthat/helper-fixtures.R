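# shared fixtures: tiny hand-built series and configs

sbp_spec <- function() default_panel()$sBP
hdl_spec <- function() default_panel()$HDL

series_of <- function(values, times = seq_along(values) * 10 - 10,
                      biomarker = "sBP") {
  biomarker_series(biomarker, times, values)
}

config_m2 <- function(...) {
  inclination_config(version = NULL, m = 2, delta_scheme = "difference",
                     weight_scheme = "constant_one", ...)
}

# independent absorption oracle: solve the linear system for the transient
# block, (I - Q) B = R, instead of powering the matrix
absorption_oracle <- function(Z) {
  absorbing <- which(diag(Z) == 1)
  transient <- setdiff(seq_len(nrow(Z)), absorbing)
  B <- solve(diag(length(transient)) - Z[transient, transient, drop = FALSE],
             Z[transient, absorbing, drop = FALSE])
  out <- matrix(0, nrow(Z), ncol(Z), dimnames = dimnames(Z))
  out[cbind(absorbing, absorbing)] <- 1
  out[transient, absorbing] <- B
  out
}
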