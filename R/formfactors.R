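# Four-Gaussian atomic scattering factor coefficients (International
# Tables for Crystallography Vol. C analytic approximation):
# f(s) = sum_i a_i exp(-b_i s^2) + c with s = sin(theta)/lambda = |q|/2.

.ff_coefficients <- local({
  tab <- rbind(
    H  = c(0.493002, 0.322912, 0.140191, 0.040810, 10.5109, 26.1257, 3.14236, 57.7997, 0.003038),
    C  = c(2.31000, 1.02000, 1.58860, 0.86500, 20.8439, 10.2075, 0.56870, 51.6512, 0.21560),
    N  = c(12.2126, 3.13220, 2.01250, 1.16630, 0.00570, 9.89330, 28.9975, 0.58260, -11.5290),
    O  = c(3.04850, 2.28680, 1.54630, 0.86700, 13.2771, 5.70110, 0.32390, 32.9089, 0.25080),
    S  = c(6.90530, 5.20340, 1.43790, 1.58630, 1.46790, 22.2151, 0.25360, 56.1720, 0.86690),
    P  = c(6.43450, 4.17910, 1.78000, 1.49080, 1.90670, 27.1570, 0.52600, 68.1645, 1.11490),
    Fe = c(11.7695, 7.35730, 3.52220, 2.30450, 4.76110, 0.30720, 15.3535, 76.8805, 1.03690),
    Mg = c(5.42040, 2.17350, 1.22690, 2.30730, 2.82750, 79.2611, 0.38080, 7.19370, 0.85840),
    Zn = c(14.0743, 7.03180, 5.16520, 2.41000, 3.26550, 0.23330, 10.3163, 58.7097, 1.30410),
    Ca = c(8.62660, 7.38730, 1.58990, 1.02110, 10.4421, 0.65990, 85.7484, 178.437, 1.37510),
    Na = c(4.76260, 3.17360, 1.26740, 1.11280, 3.28500, 8.84220, 0.31360, 129.424, 0.67600),
    Cl = c(11.4604, 7.19640, 6.25560, 1.64550, 0.01040, 1.16620, 18.5194, 47.7784, -9.55740),
    K  = c(8.21860, 7.43980, 1.05190, 0.86590, 12.7949, 0.77480, 213.187, 41.6841, 1.42280),
    Mn = c(11.2819, 7.35730, 3.01930, 2.24410, 5.34090, 0.34320, 17.8674, 83.7543, 1.08960),
    Se = c(17.0006, 5.81960, 3.97310, 4.35430, 2.40980, 0.27260, 15.2372, 43.8163, 2.84090),
    Cu = c(13.3380, 7.16760, 5.61580, 1.67350, 3.58280, 0.24700, 11.3966, 64.8126, 1.19100),
    Ni = c(12.8376, 7.29200, 4.44380, 2.38000, 3.87850, 0.25650, 12.1763, 66.3421, 1.03410),
    Co = c(12.2841, 7.34090, 4.00340, 2.34880, 4.27910, 0.27840, 13.5359, 71.1692, 1.01180),
    Br = c(17.1789, 5.23580, 5.63770, 3.98510, 2.17230, 16.5796, 0.26090, 41.4328, 2.95570),
    I  = c(20.1472, 18.9949, 7.51380, 2.27350, 4.34700, 0.38140, 27.7660, 66.8776, 4.07120)
  )
  colnames(tab) <- c("a1", "a2", "a3", "a4", "b1", "b2", "b3", "b4", "c")
  tab
})

#' Atomic scattering factor
#'
#' Evaluates the four-Gaussian analytic approximation to the x-ray atomic
#' form factor at the given scattering-vector lengths.
#'
#' @param element element symbol (case as in the periodic table; matched
#'   case-insensitively).
#' @param qmag scattering-vector length |q| = 1/d (inverse Angstrom).
#' @return numeric vector of form-factor values (electrons).
#' @export
form_factor <- function(element, qmag) {
  key <- paste0(toupper(substr(element, 1, 1)),
                tolower(substr(element, 2, 2)))
  key <- sub(" +$", "", key)
  if (!key %in% rownames(.ff_coefficients))
    stop("no form-factor coefficients for element '", element, "'")
  cf <- unname(.ff_coefficients[key, ])
  s2 <- (qmag / 2)^2
  cf[1] * exp(-cf[5] * s2) + cf[2] * exp(-cf[6] * s2) +
    cf[3] * exp(-cf[7] * s2) + cf[4] * exp(-cf[8] * s2) + cf[9]
}
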