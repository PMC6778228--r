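#' Define a generative cell archetype
#'
#' An archetype is the ground-truth description of one simulated cell class:
#' its spike waveform width, baseline firing rate, multiplicative attention and
#' drug gains, trial-to-trial gain variance, and interspike-interval (gamma
#' renewal) regularity. Populations of cells drawn from a panel of archetypes
#' feed every downstream stage with known truth.
#'
#' @param name label for the archetype (e.g. `"B1"`, `"N3"`).
#' @param p2t_mean_us,p2t_sd_us mean and SD of the waveform trough-to-peak
#'   time, in microseconds. Widths at or below 250 us define narrow spiking
#'   cells downstream.
#' @param base_rate_hz baseline firing rate in spikes/s (attend-away, no drug).
#' @param attention_gain multiplicative rate gain applied after cue onset on
#'   attend-RF trials; 1 means no attentional modulation.
#' @param drug_gain multiplicative rate gain on drug-on trials; values above 1
#'   emulate cholinergic excitation, below 1 receptor blockade.
#' @param attention_gain_drug_scale factor by which the drug scales the
#'   attentional gain *excess*: under drug the attend-RF gain becomes
#'   `1 + attention_gain_drug_scale * (attention_gain - 1)`.
#' @param gain_var trial-to-trial gain variance `sigma2_g >= 0` of the
#'   multiplicative excitability gain (gamma with mean 1).
#' @param gain_var_attend_scale factor on `gain_var` for attend-RF trials;
#'   values below 1 emulate attentional stabilization of excitability.
#' @param gain_var_drug_scale factor on `gain_var` for drug-on trials; values
#'   above 1 emulate variability increases under receptor blockade.
#' @param isi_shape gamma renewal shape `kappa > 0`: 1 gives Poisson-like
#'   irregular trains, larger values more regular trains (expected
#'   `Lv = 3 / (2 * kappa + 1)`).
#' @return an object of class `cell_archetype`.
#' @seealso [archetype_panel()], [simulate_cell()]
#' @export
cell_archetype <- function(name,
                           p2t_mean_us, p2t_sd_us = 0,
                           base_rate_hz,
                           attention_gain = 1,
                           drug_gain = 1,
                           attention_gain_drug_scale = 1,
                           gain_var = 0,
                           gain_var_attend_scale = 1,
                           gain_var_drug_scale = 1,
                           isi_shape = 1) {
  stopifnot(
    is.character(name), length(name) == 1L,
    p2t_mean_us > 0, p2t_sd_us >= 0,
    base_rate_hz > 0,
    attention_gain > 0, drug_gain > 0,
    attention_gain_drug_scale >= 0,
    gain_var >= 0, gain_var_attend_scale >= 0, gain_var_drug_scale >= 0,
    isi_shape > 0
  )
  structure(
    list(
      name = name,
      p2t_mean_us = p2t_mean_us, p2t_sd_us = p2t_sd_us,
      base_rate_hz = base_rate_hz,
      attention_gain = attention_gain,
      drug_gain = drug_gain,
      attention_gain_drug_scale = attention_gain_drug_scale,
      gain_var = gain_var,
      gain_var_attend_scale = gain_var_attend_scale,
      gain_var_drug_scale = gain_var_drug_scale,
      isi_shape = isi_shape
    ),
    class = "cell_archetype"
  )
}

#' @export
print.cell_archetype <- function(x, ...) {
  cat(sprintf(
    "<cell_archetype %s> P2T %g+/-%g us, %g Hz, attn gain %g, drug gain %g, sigma2_g %g, kappa %g\n",
    x$name, x$p2t_mean_us, x$p2t_sd_us, x$base_rate_hz,
    x$attention_gain, x$drug_gain, x$gain_var, x$isi_shape
  ))
  invisible(x)
}

#' Default seven-archetype panel
#'
#' A panel of four broad (B1-B4) and three narrow (N1-N3) spiking archetypes
#' that differ along waveform width, firing rate, spiking regularity,
#' attentional modulation and gain variance -- the dimensions along which cell
#' clusters separate in prefrontal recordings. N3 emulates the putative
#' fast-spiking class: very narrow spikes, high rates, regular trains (large
#' `isi_shape`, hence small Lv) and low gain variance.
#'
#' The `drug` argument selects the pharmacological profile of the drug-on
#' trials: `"ACh"` raises rates and lowers gain variance (cholinergic
#' excitation), `"Scop"` and `"Mec"` lower rates, raise gain variance and
#' shrink the attentional gain (muscarinic/nicotinic blockade). For `"Mec"`
#' the attentional gain of broad cells is left untouched, mirroring a
#' nicotinic contribution to attentional modulation confined to narrow
#' spiking cells.
#'
#' @param drug one of `"ACh"`, `"Scop"`, `"Mec"`.
#' @return a named list of [cell_archetype()] objects.
#' @export
archetype_panel <- function(drug = c("ACh", "Scop", "Mec")) {
  drug <- match.arg(drug)
  base <- list(
    cell_archetype("B1", 480, 15, 8,  attention_gain = 1.35, gain_var = 0.45,
                   isi_shape = 1.0),
    cell_archetype("B2", 430, 15, 20, attention_gain = 1.80, gain_var = 0.10,
                   isi_shape = 0.5),
    cell_archetype("B3", 530, 15, 4,  attention_gain = 1.10, gain_var = 0.60,
                   isi_shape = 2.0),
    cell_archetype("B4", 395, 15, 14, attention_gain = 1.60, gain_var = 0.20,
                   isi_shape = 1.4),
    cell_archetype("N1", 215, 10, 18, attention_gain = 1.15, gain_var = 0.50,
                   isi_shape = 0.7),
    cell_archetype("N2", 240, 10, 5,  attention_gain = 1.55, gain_var = 0.30,
                   isi_shape = 1.7),
    cell_archetype("N3", 165, 10, 40, attention_gain = 1.45, gain_var = 0.05,
                   isi_shape = 4.0)
  )
  names(base) <- vapply(base, `[[`, "", "name")
  prof <- switch(drug,
    ACh = list(drug_gain = c(1.45, 1.30, 1.50, 1.60, 1.55, 1.40, 1.70),
               ag_scale  = rep(0.75, 7),
               gv_scale  = rep(0.75, 7)),
    Scop = list(drug_gain = c(0.65, 0.70, 0.60, 0.65, 0.55, 0.60, 0.55),
                ag_scale  = rep(0.55, 7),
                gv_scale  = c(rep(1.5, 4), rep(1.9, 3))),
    Mec = list(drug_gain = c(0.70, 0.75, 0.70, 0.70, 0.65, 0.70, 0.65),
               ag_scale  = c(rep(1.0, 4), rep(0.6, 3)),
               gv_scale  = c(rep(1.5, 4), rep(1.8, 3)))
  )
  for (i in seq_along(base)) {
    base[[i]]$drug_gain <- prof$drug_gain[i]
    base[[i]]$attention_gain_drug_scale <- prof$ag_scale[i]
    base[[i]]$gain_var_drug_scale <- prof$gv_scale[i]
    base[[i]]$gain_var_attend_scale <- 0.7
  }
  base
}
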