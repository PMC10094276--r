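# erf/erfinv oracles independent of the pracma routines the package uses
erf_ind <- function(z) 2 * stats::pnorm(z * sqrt(2)) - 1
erfinv_ind <- function(p) stats::qnorm((p + 1) / 2) / sqrt(2)

# reference kinetic and time-model parameter sets used as regeneration inputs
tbl_kin <- list(
  total = data.frame(group = c("0%", "4%", "8%", "12%"),
                     k1 = c(0.94972, 0.95896, 0.98067, 0.96797),
                     k2 = c(0.066870, 0.056627, 0.047707, 0.032758)),
  salt = data.frame(group = c("0%", "4%", "8%", "12%"),
                    k1 = c(0.99072, 0.99204, 0.99316, 0.99345),
                    k2 = c(0.010715, 0.009633, 0.008951, 0.008060)))
tbl_power <- data.frame(group = c("0%", "4%", "8%", "12%"),
                        A = c(0.026587, 0.025606, 0.024312, 0.022290),
                        b = 0.212376,
                        c = c(0.005467, 0.005471, 0.005456, 0.005470))
tbl_exp <- data.frame(group = c("0%", "4%", "8%", "12%"),
                      A = c(0.053269, 0.051846, 0.0523298, 0.04943),
                      b = c(0.408018, 0.3930302, 0.3473287, 0.33598))
tbl_slope <- data.frame(group = c("0%", "4%", "8%", "12%"),
                        de = c(2.58e-9, 2.25e-9, 2.20e-9, 2.35e-9),
                        K = c(-0.1060, -0.1272, -0.1697, -0.2088))
de_one_way <- c("0%" = 1.29e-9, "4%" = 1.22e-9, "8%" = 1.20e-9, "12%" = 1.15e-9)

# driving-force line implied by the slope-method law, times in hours
slope_line <- function(de, K, L, times_h) {
  (2 / L) * sqrt(de * times_h * 3600 / pi) + K
}

rel_err <- function(est, truth) abs(est - truth) / abs(truth)
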