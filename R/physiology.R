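#' Maximal quantum efficiency of photosystem II
#'
#' Computed from dark-adapted minimum (`F0`) and maximum (`Fm`)
#' fluorescence as `(Fm - F0) / Fm`. Healthy, non-stressed leaves fall in
#' the 0.75-0.85 band.
#'
#' @param F0 minimum fluorescence of the dark-adapted leaf (>= 0).
#' @param Fm maximum fluorescence (> 0, >= F0).
#' @return Fv/Fm in \[0, 1\]; vectorized.
#' @examples
#' fvFm(1, 5)  # 0.8
#' @export
fvFm <- function(F0, Fm) {
  if (any(Fm <= 0)) stop("Fm must be positive")
  if (any(F0 > Fm)) stop("F0 exceeds Fm: measurement order error")
  (Fm - F0) / Fm
}

#' Operating quantum efficiency of photosystem II
#'
#' Computed under actinic light from the light-adapted maximum (`FmPrime`)
#' and steady-state (`Fs`) fluorescence as `(Fm' - Fs) / Fm'`.
#'
#' @param FmPrime light-adapted maximum fluorescence (> 0, >= Fs).
#' @param Fs steady-state fluorescence (>= 0).
#' @return Phi(PSII) in \[0, 1\]; vectorized.
#' @examples
#' phiPsii(4, 2.5)  # 0.375
#' @export
phiPsii <- function(FmPrime, Fs) {
  if (any(FmPrime <= 0)) stop("Fm' must be positive")
  if (any(Fs > FmPrime)) stop("Fs exceeds Fm': measurement order error")
  (FmPrime - Fs) / FmPrime
}

#' Apparent leaf absorptivity from reflectance
#'
#' `Abs = 1 - R / NI` from the red (`R`) and near-infrared (`NI`)
#' reflectance images.
#'
#' @param R red reflectance (>= 0).
#' @param NI near-infrared reflectance (> 0).
#' @return Absorptivity; vectorized.
#' @export
absorptivity <- function(R, NI) {
  if (any(NI <= 0)) stop("NI must be positive")
  1 - R / NI
}

#' Apparent photosynthetic electron transport rate
#'
#' `ETR = PhiPSII * PPFD * 0.5 * Abs`, where 0.5 is the fraction of
#' absorbed light directed to the PSII antennae.
#'
#' @param phiPsii operating quantum efficiency of PSII (>= 0).
#' @param Abs apparent leaf absorptivity (>= 0).
#' @param PPFD photosynthetic photon flux density in umol m-2 s-1
#'   (default 370, the actinic intensity near typical growth light).
#' @return ETR in umol electrons m-2 s-1; vectorized and linear in each
#'   argument.
#' @examples
#' etr(0.405, 0.746)  # ~55.9 at PPFD 370
#' @export
etr <- function(phiPsii, Abs, PPFD = 370) {
  if (any(c(phiPsii, Abs, PPFD) < 0)) stop("all ETR inputs must be >= 0")
  phiPsii * PPFD * 0.5 * Abs
}

#' Convert a SPAD greenness reading to areal chlorophyll content
#'
#' `chlorophyll = 99 * SPAD / (144 - SPAD)` in ug cm-2, strictly increasing
#' on \[0, 144) with a fixed point at 45.
#'
#' @param SPAD relative SPAD meter value in \[0, 144).
#' @return Chlorophyll content in ug cm-2; vectorized.
#' @examples
#' spadToChlorophyll(45)  # 45
#' @export
spadToChlorophyll <- function(SPAD) {
  if (any(SPAD < 0 | SPAD >= 144)) {
    stop("SPAD must lie in [0, 144): the conversion has a pole at 144")
  }
  99 * SPAD / (144 - SPAD)
}

#' Malondialdehyde content from thiobarbituric-acid absorbance
#'
#' Beer-Lambert quantification of the lipid-peroxidation product MDA: the
#' non-specific 600 nm absorbance is subtracted from the 532 nm reading and
#' divided by the extinction coefficient 155 mM-1 cm-1 (1 cm path length,
#' the standard cuvette for this assay), giving the assay concentration in
#' mM. That concentration is scaled back through the assay dilution (total
#' assay volume over supernatant aliquot volume, 3 for the usual 1 mL
#' supernatant + 2 mL reagent) and the extract volume per gram fresh
#' weight.
#'
#' @param A532,A600 absorbances at 532 and 600 nm. If `A600 > A532` the
#'   result is clamped at 0 with a warning and a `clamped` attribute.
#' @param extractVolume extract volume in mL.
#' @param assayDilution dilution factor of the supernatant in the assay.
#' @param freshWeight tissue fresh weight in g.
#' @return MDA content in nmol per g fresh weight.
#' @examples
#' mdaContent(0.155, 0, extractVolume = 1, assayDilution = 3,
#'            freshWeight = 1)  # 3 nmol / g
#' @export
mdaContent <- function(A532, A600, extractVolume, assayDilution = 3,
                       freshWeight = 1) {
  if (any(extractVolume <= 0) || any(freshWeight <= 0) ||
      any(assayDilution <= 0)) {
    stop("volumes, dilution and fresh weight must be positive")
  }
  delta <- A532 - A600
  clamped <- delta < 0
  if (any(clamped)) {
    warning("A600 exceeds A532: negative signal clamped at 0")
    delta[clamped] <- 0
  }
  concAssay <- delta / 155           # mM = umol per mL in the assay
  nmolPerG <- concAssay * assayDilution * extractVolume / freshWeight * 1000
  if (any(clamped)) attr(nmolPerG, "clamped") <- clamped
  nmolPerG
}

#' Compare internal and external leaf areas of interest
#'
#' Fluorescence imaging selects areas of interest (AOI) in the central
#' (internal) and outer (external) zones of each leaf; this summarises the
#' zone means and their difference, used to assess whether photosynthetic
#' efficiency varies over the leaf surface.
#'
#' @param measurements data.frame with columns `leaf`, `zone` (`"internal"`
#'   or `"external"`) and `value`; every leaf needs at least one AOI per
#'   zone.
#' @return data.frame with one row per leaf: `leaf`, `internal`,
#'   `external`, `difference` (internal - external).
#' @examples
#' aoiCompare(data.frame(leaf = 1, zone = c("internal", "internal",
#'                                          "external", "external"),
#'                       value = c(0.8, 0.8, 0.7, 0.9)))
#' @export
aoiCompare <- function(measurements) {
  stopifnot(all(c("leaf", "zone", "value") %in% names(measurements)))
  if (!all(measurements$zone %in% c("internal", "external"))) {
    stop("zone must be 'internal' or 'external'")
  }
  out <- lapply(split(measurements, measurements$leaf), function(d) {
    int <- d$value[d$zone == "internal"]
    ext <- d$value[d$zone == "external"]
    if (!length(int) || !length(ext)) {
      stop("leaf ", d$leaf[1L], " lacks a measurement in one zone")
    }
    data.frame(leaf = d$leaf[1L], internal = mean(int), external = mean(ext),
               difference = mean(int) - mean(ext))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Bundled leaf chlorophyll-fluorescence measurements of four cultivars
#'
#' Returns the published per-cultivar means (and standard errors) of the
#' chlorophyll-fluorescence and reflectance parameters for the two endive
#' cultivars ('Domari', 'Myrna') and the two escarole cultivars ('Flester',
#' 'Confiance'): Fv/Fm, Phi(PSII), ETR, absorptivity, chlorophyll content
#' and the photochemical reflectance index. The ETR column can be
#' recomputed from the Phi(PSII) and absorptivity columns with [etr()] at
#' PPFD 370.
#'
#' @return data.frame with one row per cultivar.
#' @examples
#' tab <- fluorescenceTable()
#' etr(tab$phi_psii, tab$abs)  # matches tab$etr within input rounding
#' @export
fluorescenceTable <- function() {
  read.delim(system.file("extdata", "cultivar_fluorescence.tsv",
                         package = "leafGCN"),
             stringsAsFactors = FALSE)
}
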