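# Independent Gaussian vergence-propagation oracle: traces a trial
# spectacle refraction through the cornea (thin lens at the corneal
# plane), translates the reduced vergence to the IOL plane, adds the IOL
# power, and requires focus at the formula's optical axial length. The
# refraction is solved by bisection, never by the closed-form expression
# under test.
oracle_refraction <- function(corneal_power, elp, lopt, iol_power,
                              na = 1.336, vertex = 12) {
  g <- function(R) {
    Rc <- R / (1 - vertex / 1000 * R)
    V1 <- Rc + corneal_power
    V1p <- V1 / (1 - (elp / 1000) * V1 / na)
    V1p + iol_power - 1000 * na / (lopt - elp)
  }
  # upper bracket must stay below the vergence singularity where the
  # corneal-plane rays would focus at the IOL plane itself
  rc_max <- 1000 * na / elp - corneal_power
  lo <- -45
  hi <- min(45, rc_max / (1 + 0.001 * vertex * rc_max) - 1e-6)
  stopifnot(g(lo) < 0, g(hi) > 0)
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    if (g(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Oracle wrappers resolving each formula's ELP/optical-AL geometry via
# the package's (separately unit-tested) intermediates, with the
# vergence step independent of the closed forms.
oracle_srkt <- function(al, km, constants, p) {
  z <- srkt_intermediates(al, km, constants)
  oracle_refraction(1000 * 0.333 / z$r, z$acd_est, z$lopt, p)
}
oracle_holladay1 <- function(al, km, constants, p) {
  z <- holladay1_intermediates(al, km, constants)
  oracle_refraction(1000 * (1 / 3) / z$r, z$elp, z$alm, p)
}
oracle_hofferq <- function(al, km, constants, p) {
  z <- hofferq_intermediates(al, km, constants)
  oracle_refraction(km, z$acd_pred + 0.05, al, p)
}
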