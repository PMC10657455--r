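#' @include AllClasses.R
NULL

#' PAM chlorophyll-fluorescence trace
#'
#' One row per saturating pulse: time (s), protocol phase (\code{D},
#' \code{L1}, \code{L2}, \code{D2}), steady-state fluorescence yield
#' \code{F}, post-pulse maximal yield \code{Fm_prime} and actinic irradiance
#' \code{I} (umol photons m-2 s-1). The dark-adapted reference \code{F0} and
#' \code{Fm} are held separately.
#'
#' @slot records data.frame with columns \code{time}, \code{phase},
#'   \code{F}, \code{Fm_prime}, \code{I}.
#' @slot F0,Fm dark-adapted minimal and maximal fluorescence yields.
#' @export
setClass("PAMTrace",
  representation(records = "data.frame", F0 = "numeric", Fm = "numeric")
)

setValidity("PAMTrace", function(object) {
  msg <- character()
  need <- c("time", "phase", "F", "Fm_prime", "I")
  if (!all(need %in% names(object@records)))
    msg <- c(msg, paste("records must have columns:", paste(need, collapse = ", ")))
  if (!(object@Fm >= object@F0 && object@F0 > 0))
    msg <- c(msg, "dark reference must satisfy Fm >= F0 > 0")
  if (all(need %in% names(object@records)) &&
      any(object@records$Fm_prime <= 0))
    msg <- c(msg, "Fm_prime must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a PAMTrace
#' @param records data.frame (see [PAMTrace-class]).
#' @param F0,Fm dark-adapted reference yields.
#' @return a [PAMTrace-class].
#' @export
PAMTrace <- function(records, F0, Fm) {
  records$phase <- as.character(records$phase)
  new("PAMTrace", records = records, F0 = as.numeric(F0), Fm = as.numeric(Fm))
}

setMethod("show", "PAMTrace", function(object) {
  cat(sprintf("PAMTrace: %d pulses, phases %s; F0=%.3g Fm=%.3g (Fv/Fm=%.3f)\n",
              nrow(object@records),
              paste(unique(object@records$phase), collapse = ","),
              object@F0, object@Fm, (object@Fm - object@F0) / object@Fm))
  invisible(object)
})

#' Photosynthetic parameters from a single saturating pulse
#'
#' Standard pulse-amplitude-modulation quantities:
#' \deqn{Y(II) = (Fm' - F)/Fm', \quad NPQ = (Fm - Fm')/Fm',}
#' \deqn{rETR = Y(II) \cdot I, \quad Fv/Fm = (Fm - F0)/Fm.}
#' \code{F > Fm'} (measurement noise) clamps Y(II) to 0 with a warning;
#' \code{Fm' > Fm} yields a negative NPQ, reported as computed with a
#' data-quality warning.
#'
#' @param F steady-state fluorescence yield in actinic light.
#' @param Fm_prime maximal yield after a saturating pulse in actinic light.
#' @param I actinic irradiance, umol photons m-2 s-1.
#' @param F0,Fm dark-adapted reference yields.
#' @return named list: \code{Y_II}, \code{NPQ}, \code{rETR}, \code{Fv_Fm}.
#' @examples
#' pamParameters(F = 300, Fm_prime = 600, I = 337, F0 = 240, Fm = 500)
#' @export
pamParameters <- function(F, Fm_prime, I, F0, Fm) {
  if (any(c(F, Fm_prime, F0, Fm) <= 0)) stop("fluorescence yields must be positive")
  if (Fm < F0) stop("dark reference must satisfy Fm >= F0")
  Y <- (Fm_prime - F) / Fm_prime
  if (Y < 0) {
    warning("F exceeds Fm_prime; Y(II) clamped to 0")
    Y <- 0
  }
  NPQ <- (Fm - Fm_prime) / Fm_prime
  if (NPQ < 0)
    warning("Fm_prime exceeds dark Fm: negative NPQ (check dark adaptation)")
  list(Y_II = Y, NPQ = NPQ, rETR = Y * I, Fv_Fm = (Fm - F0) / Fm)
}

#' Per-phase mean photosynthetic parameters for the D/L1/L2/D2 protocol
#'
#' Expects the dark/low-light/high-light/relaxation protocol (dark, then 22,
#' then 337 umol photons m-2 s-1, then dark relaxation). Parameters are
#' computed per pulse against the dark-adapted \code{F0}/\code{Fm} reference
#' and averaged within each phase; dark phases use I = 0, so rETR = 0 there.
#'
#' @param trace a [PAMTrace-class].
#' @param phases required phase order (default \code{D, L1, L2, D2}).
#' @return data.frame with one row per phase: mean \code{Y_II}, \code{NPQ},
#'   \code{rETR}, plus \code{I} and \code{n} pulses, and the global
#'   \code{Fv_Fm}.
#' @export
protocolSummary <- function(trace, phases = c("D", "L1", "L2", "D2")) {
  stopifnot(is(trace, "PAMTrace"))
  rec <- trace@records
  present <- unique(rec$phase)
  missing <- setdiff(phases, present)
  if (length(missing))
    stop("missing protocol phase(s): ", paste(missing, collapse = ", "))
  ord <- match(rec$phase, phases)
  if (is.unsorted(ord))
    stop("trace phases are not in protocol order ",
         paste(phases, collapse = ", "))
  rows <- lapply(phases, function(ph) {
    r <- rec[rec$phase == ph, ]
    pars <- Map(pamParameters, r$F, r$Fm_prime, r$I,
                MoreArgs = list(F0 = trace@F0, Fm = trace@Fm))
    data.frame(phase = ph,
               I = mean(r$I),
               n = nrow(r),
               Y_II = mean(vapply(pars, `[[`, numeric(1), "Y_II")),
               NPQ = mean(vapply(pars, `[[`, numeric(1), "NPQ")),
               rETR = mean(vapply(pars, `[[`, numeric(1), "rETR")),
               Fv_Fm = (trace@Fm - trace@F0) / trace@Fm)
  })
  do.call(rbind, rows)
}

#' Read / write a PAM trace CSV
#'
#' The CSV dialect: a header block of \code{# key: value} lines carrying the
#' dark reference (\code{F0}, \code{Fm}), then standard columns
#' \code{time,phase,F,Fm_prime,I}.
#'
#' @param path CSV path.
#' @return a [PAMTrace-class].
#' @export
readPamTrace <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getv <- function(key) {
    ln <- grep(paste0("^#\\s*", key, "\\s*:"), hdr, value = TRUE)
    if (!length(ln)) stop("PAM trace header lacks '", key, "'")
    as.numeric(sub(".*:\\s*", "", ln[1]))
  }
  body <- lines[!grepl("^#", lines)]
  rec <- utils::read.csv(text = paste(body, collapse = "\n"))
  PAMTrace(rec, F0 = getv("F0"), Fm = getv("Fm"))
}

#' @rdname readPamTrace
#' @param trace a [PAMTrace-class] to write.
#' @export
writePamTrace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(c("# F0: %.10g", "# Fm: %.10g"), c(trace@F0, trace@Fm)), con)
  utils::write.csv(trace@records, con, row.names = FALSE)
  invisible(path)
}

#' Synthetic PAM trace with light-saturation behaviour
#'
#' Simulates the D/L1/L2/D2 protocol for a photosystem with saturating
#' light response: Y(II) declines with irradiance as
#' \eqn{Y = Y_{dark} I_k / (I_k + I)} and NPQ builds in high light as a
#' Hill-type function of irradiance, so a generated trace always satisfies
#' Y(II)(L2) < Y(II)(L1) and NPQ(L2) > NPQ(L1). Multiplicative yield noise
#' is seeded and small.
#'
#' @param F0,Fm dark-adapted reference yields (defaults give Fv/Fm = 0.52).
#' @param I_L1,I_L2 actinic irradiances (defaults 22 and 337).
#' @param Ik light-saturation constant, umol photons m-2 s-1.
#' @param npqMax maximal NPQ.
#' @param pulsesPerPhase saturating pulses per phase.
#' @param noiseSd multiplicative noise SD on yields.
#' @param seed RNG seed.
#' @return a [PAMTrace-class].
#' @export
makePamTrace <- function(F0 = 240, Fm = 500, I_L1 = 22, I_L2 = 337,
                         Ik = 150, npqMax = 1.2, pulsesPerPhase = 5L,
                         noiseSd = 0.01, seed = 1L) {
  set.seed(seed)
  Ydark <- (Fm - F0) / Fm
  phases <- data.frame(phase = c("D", "L1", "L2", "D2"),
                       I = c(0, I_L1, I_L2, 0))
  rows <- list()
  tm <- 0
  for (i in seq_len(nrow(phases))) {
    I <- phases$I[i]
    npq <- npqMax * I^2 / (I^2 + 100^2)
    if (phases$phase[i] == "D2") npq <- 0.1 * npq  # relaxation
    Fmp <- Fm / (1 + npq)
    Y <- Ydark * Ik / (Ik + I)
    for (p in seq_len(pulsesPerPhase)) {
      tm <- tm + 30
      eps <- exp(stats::rnorm(2L, 0, noiseSd))
      FmpN <- Fmp * eps[1]
      if (I == 0) FmpN <- min(FmpN, Fm)  # dark pulses cannot exceed dark Fm
      rows[[length(rows) + 1L]] <- data.frame(
        time = tm, phase = phases$phase[i],
        F = FmpN * (1 - Y * eps[2]), Fm_prime = FmpN, I = I)
    }
  }
  PAMTrace(do.call(rbind, rows), F0 = F0, Fm = Fm)
}

#' Solute concentration in the snow liquid phase
#'
#' Converts a meltwater concentration to the concentration in the liquid
#' water fraction of the snowpack, assuming solutes are excluded from the
#' ice crystals: \code{c_liquid = (c_melt / concentrationFactor) / lwc}. A
#' liquid water content of 15 mass% thus concentrates meltwater values
#' about 6.7-fold; freeze-drying pre-concentration (10 to 12.5-fold in the
#' reference protocol) is divided out first.
#'
#' @param cMelt concentration in melted snow (any unit, e.g. mol/L).
#' @param lwc liquid water content, mass fraction in (0, 1].
#' @param concentrationFactor pre-concentration factor applied to the
#'   analysed sample (default 1).
#' @return concentration in the liquid phase, same unit as \code{cMelt}.
#' @examples
#' liquidPhaseConcentration(1.5e-6, lwc = 0.15)  # 1e-5
#' @export
liquidPhaseConcentration <- function(cMelt, lwc = 0.15, concentrationFactor = 1) {
  if (any(cMelt < 0)) stop("concentrations must be non-negative")
  if (any(lwc <= 0 | lwc > 1)) stop("lwc must lie in (0, 1]")
  if (any(concentrationFactor <= 0)) stop("concentrationFactor must be positive")
  (cMelt / concentrationFactor) / lwc
}
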