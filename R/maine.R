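# Default region set for the synthetic generator: the 16 Maine counties with
# plausible (synthetic, not census-extracted) population weights and
# county-level socioeconomic covariates. The weights and covariates are
# stand-ins shaped like 2010-era Maine — larger, richer coastal south
# (Cumberland, York), poorer rural north — so that income-linked payer
# assignment produces realistic county gradients. Replace with real census
# figures for production analyses.

#' Default county table for the synthetic generator (synthetic values)
#'
#' @return tibble with `county`, `pop_weight` (sums to 1), `median_income`
#'   (USD/yr), `pct_poverty`, `pct_bachelors`.
#' @export
default_county_table <- function() {
  t <- tibble::tribble(
    ~county,        ~pop_weight, ~median_income, ~pct_poverty, ~pct_bachelors,
    "Androscoggin",      0.0809,          44470,         14.2,           17.8,
    "Aroostook",         0.0541,          36574,         17.4,           15.1,
    "Cumberland",        0.2122,          56365,         10.8,           38.7,
    "Franklin",          0.0231,          41061,         15.7,           21.3,
    "Hancock",           0.0410,          46148,         12.4,           31.4,
    "Kennebec",          0.0920,          45973,         13.2,           23.5,
    "Knox",              0.0298,          45264,         12.6,           29.1,
    "Lincoln",           0.0259,          48527,         11.4,           28.6,
    "Oxford",            0.0434,          40420,         15.9,           17.0,
    "Penobscot",         0.1157,          42658,         16.0,           22.4,
    "Piscataquis",       0.0131,          34016,         18.2,           14.6,
    "Sagadahoc",         0.0265,          54358,          9.6,           30.1,
    "Somerset",          0.0389,          36647,         18.1,           14.3,
    "Waldo",             0.0290,          41312,         15.9,           23.0,
    "Washington",        0.0245,          34859,         19.4,           15.9,
    "York",              0.1475,          55008,          9.9,           29.9)
  t$pop_weight <- t$pop_weight / sum(t$pop_weight)
  t
}

# Five-year age-band weights shaped like an old-state age pyramid
# (median age ~43). Uniform ages within a band; 85+ spans 85-95.
default_age_band_weights <- function() {
  w <- c(5.2, 5.6, 6.1, 6.6, 5.6, 5.4, 5.4, 6.0, 6.9, 7.9, 8.2, 7.5,
         6.6, 5.0, 3.9, 3.0, 2.4, 2.3)
  setNames(w / sum(w), age_band_levels())
}
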