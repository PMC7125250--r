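# Small in-code fixtures for the agreement and estimation tests.

# a dataset-dialect data frame from per-lesion paired profiles
paired_df <- function(profiles) {
  do.call(rbind, lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    nt <- length(p$times)
    data.frame(ID = i, PTID = i,
               OPER = rep(c("LOCAL", "CENTRAL"), each = nt),
               TIME = rep(p$times, 2),
               DV = c(p$local, p$central),
               BLQ = as.integer(c(p$local, p$central) == 0.25))
  }))
}

# paired-scan table with prescribed measurability-discordance counts
blq_fixture <- function(n_pairs, n_local_only, n_central_only) {
  lb <- c(rep(1L, n_local_only), rep(0L, n_pairs - n_local_only))
  cb <- c(rep(0L, n_local_only), rep(1L, n_central_only),
          rep(0L, n_pairs - n_local_only - n_central_only))
  data.frame(ID = seq_len(n_pairs), PTID = 1L,
             OPER = rep(c("LOCAL", "CENTRAL"), each = n_pairs),
             TIME = 0,
             DV = c(ifelse(lb == 1L, 0.25, 2), ifelse(cb == 1L, 0.25, 2)),
             BLQ = c(lb, cb))
}

table1_local_population <- function() {
  tgi_population(tgi_params(3.1, 0.0012, 0.0077),
                 omega2 = c(0.31, 0.20, 0.44), sigma_add = 0.43)
}
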