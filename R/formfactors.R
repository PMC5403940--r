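## Atomic scattering factors: 4-Gaussian + constant parameterization
## (International Tables for Crystallography, Vol. C, Table 6.1.1.4).
## f(q) = sum_i a_i exp(-b_i s^2) + c with s = q / (4 pi) = sin(theta)/lambda.

.cm_table <- local({
  m <- rbind(
    H  = c(1,  0.493002, 0.322912, 0.140191, 0.040810, 10.5109, 26.1257, 3.14236, 57.7997, 0.003038),
    C  = c(6,  2.31000,  1.02000,  1.58860,  0.865000, 20.8439, 10.2075, 0.568700, 51.6512, 0.215600),
    N  = c(7,  12.2126,  3.13220,  2.01250,  1.16630,  0.005700, 9.89330, 28.9975, 0.582600, -11.529),
    O  = c(8,  3.04850,  2.28680,  1.54630,  0.867000, 13.2771, 5.70110, 0.323900, 32.9089, 0.250800),
    NA. = c(11, 4.76260, 3.17360,  1.26740,  1.11280,  3.28500, 8.84220, 0.313600, 129.424, 0.676000),
    MG = c(12, 5.42040,  2.17350,  1.22690,  2.30730,  2.82750, 79.2611, 0.380800, 7.19370, 0.858400),
    P  = c(15, 6.43450,  4.17910,  1.78000,  1.49080,  1.90670, 27.1570, 0.526000, 68.1645, 1.11490),
    S  = c(16, 6.90530,  5.20340,  1.43790,  1.58630,  1.46790, 22.2151, 0.253600, 56.1720, 0.866900),
    CL = c(17, 11.4604,  7.19640,  6.25560,  1.64550,  0.010400, 1.16620, 18.5194, 47.7784, -9.5574),
    K  = c(19, 8.21860,  7.43980,  1.05190,  0.865900, 12.7949, 0.774800, 213.187, 41.6841, 1.42280),
    CA = c(20, 8.62660,  7.38730,  1.58990,  1.02110,  10.4421, 0.659900, 85.7484, 178.437, 1.37510),
    FE = c(26, 11.7695,  7.35730,  3.52220,  2.30450,  4.76110, 0.307200, 15.3535, 76.8805, 1.03690),
    ZN = c(30, 14.0743,  7.03180,  5.16520,  2.41000,  3.26550, 0.233300, 10.3163, 58.7097, 1.30410)
  )
  rownames(m)[rownames(m) == "NA."] <- "NA"
  colnames(m) <- c("Z", paste0("a", 1:4), paste0("b", 1:4), "c")
  m
})

.norm_element <- function(elements) toupper(trimws(elements))

#' Elements with tabulated scattering-factor parameters
#'
#' @return Character vector of recognized element symbols.
#' @export
known_elements <- function() rownames(.cm_table)

#' Atomic number (electron count) of an element
#'
#' @param elements Character vector of element symbols.
#' @return Integer vector of atomic numbers.
#' @export
atomic_number <- function(elements) {
  el <- .norm_element(elements)
  bad <- setdiff(unique(el), rownames(.cm_table))
  if (length(bad))
    stop("no scattering-factor parameters for element(s): ",
         paste(bad, collapse = ", "))
  as.integer(.cm_table[el, "Z"])
}

#' Atomic scattering factor f(q)
#'
#' Evaluates the q-dependent X-ray scattering factor of a free atom using the
#' standard four-Gaussian-plus-constant fit, with q the momentum transfer
#' magnitude in inverse Angstrom (q = 4 pi sin(theta) / lambda).
#'
#' @param element Single element symbol (e.g. "C").
#' @param q Numeric vector of momentum-transfer magnitudes, 1/Angstrom.
#' @return Numeric vector of scattering factors (electrons).
#' @export
form_factor <- function(element, q) {
  el <- .norm_element(element)
  if (length(el) != 1L) stop("'element' must be a single symbol")
  if (!el %in% rownames(.cm_table))
    stop("no scattering-factor parameters for element: ", el)
  p <- .cm_table[el, ]
  s2 <- (q / (4 * pi))^2
  p["a1"] * exp(-p["b1"] * s2) + p["a2"] * exp(-p["b2"] * s2) +
    p["a3"] * exp(-p["b3"] * s2) + p["a4"] * exp(-p["b4"] * s2) + p["c"]
}
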