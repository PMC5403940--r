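# Shared fixtures: small detectors and toy complexes, cached per session.
# Detector sizes are chosen so the edge reaches past 4 A resolution while
# keeping per-pattern cost low.

.fx <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fx[[key]])) .fx[[key]] <- force(expr)
  .fx[[key]]
}

det48 <- function() cached("det48", beam_detector(
  n_fast = 48L, n_slow = 48L, pixel_size = 0.55, distance = 50))
qm48 <- function() cached("qm48", build_qmap(det48()))

det40 <- function() cached("det40", beam_detector(
  n_fast = 40L, n_slow = 40L, pixel_size = 0.65, distance = 50))
qm40 <- function() cached("qm40", build_qmap(det40()))

det32 <- function() cached("det32", beam_detector(
  n_fast = 32L, n_slow = 32L, pixel_size = 0.75, distance = 50))
qm32 <- function() cached("qm32", build_qmap(det32()))

toy80 <- function() cached("toy80", make_toy_complex(50L, 30L, seed = 7L))
toy50 <- function() cached("toy50", make_toy_complex(35L, 15L, seed = 11L))

# a small smooth (non-speckled) synthetic pattern: intensity g(|q|)
radial_test_pattern <- function(qm, g = function(q) 1e3 * exp(-2 * q^2)) {
  intens <- rep(NA_real_, length(qm$qmag))
  intens[qm$mask] <- g(qm$qmag[qm$mask])
  spidock:::new_pattern(intens, c(0, 0, 0))
}

# hand-written fixed-column PDB records (for parser tests)
pdb_record <- function(serial, name, x, y, z, element = "", resno = serial,
                       resid = "GLY", chain = "A") {
  sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, resid, chain, resno, x, y, z, 1.0, 0.0, element)
}

write_fixture_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# direction on the unit sphere that the (alpha, beta) pair maps the beam
# axis to in the model frame; used to compare reduced-representation
# orientation recovery, which cannot see the in-plane angle gamma
beam_direction <- function(alpha, beta) {
  a <- alpha * pi / 180; b <- beta * pi / 180
  c(-sin(b) * cos(a), sin(b) * sin(a), cos(b))
}

angle_between <- function(u, v) {
  acos(pmin(1, pmax(-1, sum(u * v) /
                      sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
}
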