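#' Composition records and brine specifications
#'
#' Constructors for the basic composition containers used throughout the
#' package. A composition record holds one timepoint's sample mass and its
#' moisture and salt mass fractions; a brine specification holds the brine
#' mass and its salt/water/xylitol mass fractions. All fractions are mass
#' fractions in \[0, 1\]; percentages appear only at I/O boundaries.
#'
#' @param time curing time in hours (>= 0).
#' @param mass sample (or brine) mass in grams (> 0).
#' @param moisture_frac moisture mass fraction in \[0, 1\].
#' @param salt_frac NaCl mass fraction in \[0, 1\].
#' @return `composition_record()` returns an object of class
#'   `"composition_record"`; `brine_spec()` one of class `"brine_spec"`.
#' @examples
#' meat  <- composition_record(0, mass = 10, moisture_frac = 0.74,
#'                             salt_frac = 0.0041)
#' brine <- brine_spec(mass = 40, salt_frac = 0.08, water_frac = 0.92)
#' @export
composition_record <- function(time, mass, moisture_frac, salt_frac) {
  stopifnot(is.numeric(time), time >= 0, is.numeric(mass))
  if (mass <= 0) stop_brinesim("sample mass must be positive", "invalid_composition")
  if (moisture_frac < 0 || moisture_frac > 1 || salt_frac < 0 || salt_frac > 1)
    stop_brinesim("fractions must lie in [0, 1]", "invalid_composition")
  if (moisture_frac + salt_frac > 1 + 1e-12)
    stop_brinesim("moisture_frac + salt_frac exceeds 1", "invalid_composition")
  structure(list(time = time, mass = mass, moisture_frac = moisture_frac,
                 salt_frac = salt_frac), class = "composition_record")
}

#' @param water_frac water mass fraction of the brine.
#' @param xylitol_frac xylitol mass fraction of the brine (group label; the
#'   polyol is not modelled as a second diffusing species).
#' @rdname composition_record
#' @export
brine_spec <- function(mass, salt_frac, water_frac, xylitol_frac = 0) {
  if (mass <= 0) stop_brinesim("brine mass must be positive", "invalid_composition")
  f <- c(salt_frac, water_frac, xylitol_frac)
  if (any(f < 0) || any(f > 1) || sum(f) > 1 + 1e-12)
    stop_brinesim("brine fractions must be in [0, 1] and sum to at most 1",
                  "invalid_composition")
  structure(list(mass = mass, salt_frac = salt_frac, water_frac = water_frac,
                 xylitol_frac = xylitol_frac), class = "brine_spec")
}

#' @param z0 initial aqueous-phase salt fraction of the tissue.
#' @param ze equilibrium aqueous-phase salt fraction (shared by tissue and
#'   brine at equilibrium).
#' @rdname composition_record
#' @export
equilibrium_state <- function(z0, ze) {
  stopifnot(z0 >= 0, z0 <= 1, ze >= 0, ze <= 1)
  if (z0 >= ze)
    stop_brinesim("salt uptake requires z0 < ze", "invalid_composition")
  structure(list(z0 = z0, ze = ze), class = "equilibrium_state")
}

#' Aqueous-phase salt content
#'
#' The thermodynamically relevant salt concentration for brine-tissue
#' exchange is the salt mass over the (water + salt) mass of the phase,
#' Z = Xs / (Xw + Xs); mass transfer during curing happens in the aqueous
#' phase, so Z rather than the whole-tissue salt fraction drives exchange.
#'
#' @param salt_frac salt mass fraction of the phase.
#' @param moisture_frac water mass fraction of the phase.
#' @return the aqueous-phase salt fraction, in \[0, 1\].
#' @examples
#' aqueous_salt_fraction(0.047, 0.70)  # ~0.0629
#' @export
aqueous_salt_fraction <- function(salt_frac, moisture_frac) {
  stopifnot(all(salt_frac >= 0), all(moisture_frac >= 0))
  tot <- moisture_frac + salt_frac
  if (any(tot == 0))
    stop_brinesim("aqueous phase has zero mass: composition undefined",
                  "undefined_composition")
  salt_frac / tot
}

#' Equilibrium aqueous-phase salt content of a closed meat-brine system
#'
#' At equilibrium the aqueous-phase salt content of the tissue equals that of
#' the brine; with both phases closed to the exterior it is fixed by the
#' two-phase salt mass balance: total salt mass over total (water + salt)
#' mass of the combined system,
#' \deqn{Z_e = \frac{M_m X_{0s} + M_b y_{0s}}{M_m (X_{0w}+X_{0s}) + M_b (y_{0w}+y_{0s})}.}
#'
#' @param meat0 a [composition_record()] with the tissue's initial state.
#' @param brine a [brine_spec()].
#' @return the equilibrium aqueous salt fraction (scalar).
#' @examples
#' m <- composition_record(0, 10, moisture_frac = 0.74, salt_frac = 0)
#' b <- brine_spec(40, salt_frac = 0.08, water_frac = 0.92)
#' equilibrium_aqueous_salt(m, b)  # ~0.0675
#' @export
equilibrium_aqueous_salt <- function(meat0, brine) {
  stopifnot(inherits(meat0, "composition_record"), inherits(brine, "brine_spec"))
  salt  <- meat0$mass * meat0$salt_frac + brine$mass * brine$salt_frac
  aqtot <- meat0$mass * (meat0$moisture_frac + meat0$salt_frac) +
           brine$mass * (brine$water_frac + brine$salt_frac)
  if (aqtot <= 0)
    stop_brinesim("combined aqueous mass is zero", "undefined_composition")
  salt / aqtot
}

#' Complement of the normalized driving force
#'
#' The driving force Y_t = (z_t - y_t) / (z_0 - z_e) measures how far the
#' tissue's aqueous salt content still is from equilibrium with the brine;
#' its complement 1 - Y_t runs from 0 at the start of curing to 1 at
#' equilibrium (with the brine held at y_t ~ z_e) and is the response
#' regressed on sqrt(t) by the slope method.
#'
#' @param zt tissue aqueous salt fraction at time t.
#' @param yt brine aqueous salt fraction at time t.
#' @param z0 initial tissue aqueous salt fraction.
#' @param ze equilibrium aqueous salt fraction.
#' @return 1 - (zt - yt)/(z0 - ze), dimensionless.
#' @export
driving_force_complement <- function(zt, yt, z0, ze) {
  if (z0 == ze)
    stop_brinesim("z0 == ze: no concentration gradient, driving force undefined",
                  "degenerate_gradient")
  1 - (zt - yt) / (z0 - ze)
}

#' Convert a salt mass fraction to molar concentration
#'
#' Links w/w brine strength to the mol m^-3 scale used by the simulation
#' fields, via the NaCl molar mass 58.44 g mol^-1.
#'
#' @param mass_frac NaCl mass fraction.
#' @param density solution density in kg m^-3.
#' @return concentration in mol m^-3.
#' @examples
#' mass_frac_to_molar(0.08, 1056)  # ~1446 mol m^-3
#' @export
mass_frac_to_molar <- function(mass_frac, density) {
  if (any(mass_frac < 0) || any(density <= 0))
    stop_brinesim("mass fraction must be >= 0 and density > 0", "invalid_composition")
  mass_frac * density / 0.05844
}

#' Brine salt fraction after solute exchange with the tissue
#'
#' Updates the brine composition by solute conservation: salt gained by the
#' tissue since t = 0 is salt lost by the brine (and vice versa for water).
#' A well-stirred infinite-bath mode keeps the brine composition fixed at
#' its initial value.
#'
#' @param brine a [brine_spec()].
#' @param salt_gain_g grams of salt transferred into the tissue since t = 0.
#' @param water_loss_g grams of water transferred from the tissue into the
#'   brine since t = 0 (negative if the tissue took up water).
#' @param infinite_bath if `TRUE`, return the initial brine aqueous salt
#'   fraction unchanged.
#' @return the brine's aqueous-phase salt fraction at time t.
#' @export
brine_salt_after_exchange <- function(brine, salt_gain_g, water_loss_g = 0,
                                      infinite_bath = FALSE) {
  stopifnot(inherits(brine, "brine_spec"))
  if (infinite_bath)
    return(aqueous_salt_fraction(brine$salt_frac, brine$water_frac))
  salt  <- brine$mass * brine$salt_frac - salt_gain_g
  water <- brine$mass * brine$water_frac + water_loss_g
  if (salt < 0) stop_brinesim("brine salt balance went negative", "invalid_composition")
  aqueous_salt_fraction(salt / brine$mass, water / brine$mass)
}
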