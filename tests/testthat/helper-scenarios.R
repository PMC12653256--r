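# shared builders for small synthetic inputs (kept cheap: one week of 3-hourly
# fields on the default 1-degree study domain)

uniform_field <- function(u = 10, v = 0, T = 20, ...) {
  gen_windfield("uniform", u = u, v = v, T_base = T,
                time_range = c("2024-05-01 00:00", "2024-05-08 00:00"), ...)
}

mk_intervals <- function(pop, lc50, lower, upper, insecticide = "pymetrozine") {
  data.frame(population = pop, insecticide = insecticide,
             lc50 = lc50, lower = lower, upper = upper,
             stringsAsFactors = FALSE)
}

# great-circle-free planar distance in km used for trajectory error checks
planar_km <- function(lat1, lon1, lat2, lon2) {
  mlat <- (lat1 + lat2) / 2
  sqrt(((lat1 - lat2) * 111.32)^2 + ((lon1 - lon2) * 111.32 * cos(mlat * pi / 180))^2)
}

hn_gx_tables <- function() {
  tox <- load_toxicity_tables()
  list(all = tox,
       hn = tox[tox$province == "HN", ],
       gx = tox[tox$province == "GX", ])
}
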