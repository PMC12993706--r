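#!/usr/bin/env Rscript
# Stage 4: surface-temperature retrieval and decomposition.
#
# Surface temperature comes from outgoing longwave via the albedo-dependent
# emissivity; the daily between-site difference is decomposed into
# radiative (albedo, incoming shortwave/longwave, emissivity) and
# non-radiative (latent, sensible, soil heat, residual) components about
# the control site's daily state. Days failing the missingness/rain flags
# or the sign/2-degC agreement filter are dropped. The ecosystem cools
# under N addition while the understory warms -- the central scale
# dependence the decomposition is built to explain.

library(ecoforcing)

latitude <- 39.94
config <- analysis_config()
calendar <- default_season_calendar(2013:2019)
dir.create("results/decomposition", showWarnings = FALSE, recursive = TRUE)

read_site <- function(site, layer) read_halfhourly_csv(
  file.path("results/towers", sprintf("%s_%s.csv", site, layer)), site, layer)

all_dc <- NULL
for (layer in c("ecosystem", "understory")) {
  st_c <- daily_site_state(read_site("CT", layer), latitude, config)
  for (treated in c("NT", "NPT")) {
    st_t <- daily_site_state(read_site(treated, layer), latitude, config)
    dc <- decomposition_daily(st_t, st_c, calendar, config)
    all_dc <- rbind(all_dc, cbind(pair = paste0(treated, "-CT"),
                                  layer = layer, dc))
    kept <- dc[dc$kept, ]
    cat(sprintf(
      "%s-CT %s: %d days decomposed, %d kept; mean dTs_obs %+.2f degC, mean dTs_cal %+.2f degC\n",
      treated, layer, nrow(dc), nrow(kept),
      mean(kept$dts_obs), mean(kept$dts_cal)))
  }
}
write.csv(all_dc, "results/decomposition/decomposition_daily.csv",
          row.names = FALSE)
cat("\nComponent sums close on dTs_cal to machine precision by construction;\n")
cat("agreement of dTs_cal with dTs_obs validates the first-order expansion.\n")
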