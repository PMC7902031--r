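# Shared fixtures: the bench membrane/chamber and an independent
# bisection oracle for the cap-height cubic (stats::uniroot, a different
# code path from the package's Newton iteration).

beta_geom <- function() membrane_geometry(radius_a = 1.26, thickness_t = 5)
beta_chamber <- function() chamber_config(ambient_P0 = 98, headspace_V0 = 30)

oracle_cap_height <- function(v, a) {
  if (v == 0) return(0)
  stats::uniroot(function(h) pi * (h^3 / 6 + a^2 * h / 2) - v,
                 c(0, 10 * a), tol = 1e-14)$root
}
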