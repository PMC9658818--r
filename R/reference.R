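# Published benchmark accuracies for gait-transition recognition with
# motion-capture kinematics. The underlying recordings are not public, so
# these tables serve two purposes: they validate the package's reporting
# arithmetic (robustness summaries, stage-2 model selection, improvement
# deltas must reproduce the printed cells), and they document the accuracy
# regime the synthetic generator is meant to support. All values are
# percentages as printed.

#' Published stage-1 accuracy table
#'
#' Repeated ten-fold CV accuracies (%) of nine candidate classifier
#' ensembles under the eight fusion rules, together with the best single
#' member classifier of each ensemble ("single_max"). Ensembles are named
#' by their member classifier ids (see [classifier_specs()]).
#'
#' @return A data.frame with columns `ensemble`, `single_max` and one
#'   column per fusion rule.
#' @export
reference_stage1_accuracies <- function() {
  df <- read.csv(text = "ensemble;single_max;vote;max;sum;min;average;product;dt;ds
1,2;96.09;94.17;94.34;96.09;95.99;96.09;95.99;96.05;96.09
1,4;94.60;93.23;94.60;96.43;94.69;96.43;97.45;96.91;97.45
2,4;96.32;93.63;96.32;96.32;96.32;96.32;96.32;96.32;96.32
3,4;99.78;96.17;99.83;99.87;98.39;99.87;99.74;99.87;99.87
3,5;99.74;99.70;99.83;99.87;99.87;99.87;99.83;99.87;99.87
\"1,2,4\";95.99;96.83;94.66;96.77;95.90;96.77;95.90;96.60;96.73
\"1,3,5\";99.65;99.70;95.34;99.37;99.35;99.37;99.35;99.22;99.59
\"3,4,5\";99.55;99.61;99.70;99.70;98.81;99.70;99.70;99.70;99.70
\"1,3,4,5\";99.74;99.74;95.02;99.72;98.88;99.72;99.66;99.65;99.80",
                 sep = ";", stringsAsFactors = FALSE)
  df
}

#' Published missing-feature robustness accuracies
#'
#' Dempster-Shafer-fused CV accuracies (%) of seven candidate ensembles in
#' the five missing-feature-group scenarios (all features of one kinematic
#' channel removed), together with the published row mean ("average", %)
#' and the published population standard deviation of the five accuracies
#' expressed as fractions ("sd").
#'
#' @return A data.frame with columns `ensemble`, the five scenario
#'   columns `no_rt_av`, `no_rt_v`, `no_lt_av`, `no_ls_v`, `no_lf_av`,
#'   plus `average` and `sd`.
#' @export
reference_robustness_accuracies <- function() {
  read.csv(text = "ensemble;no_rt_av;no_rt_v;no_lt_av;no_ls_v;no_lf_av;average;sd
1,2;95.09;92.84;92.73;96.09;89.41;93.23;0.0231
1,4;96.55;96.50;94.24;97.27;92.60;95.43;0.0174
2,4;95.04;92.39;92.67;96.12;89.51;93.15;0.0230
3,4;98.96;98.55;95.84;99.65;93.89;97.38;0.0217
3,5;99.20;99.11;92.42;99.48;92.07;96.46;0.0344
\"3,4,5\";98.94;98.83;95.81;99.70;94.05;97.47;0.0216
\"1,3,4,5\";99.15;98.75;95.40;99.09;93.61;97.20;0.0228",
           sep = ";", stringsAsFactors = FALSE)
}

#' Published optimal feature subset
#'
#' The nine features retained by the two-stage MRMR-BMSF selection on the
#' benchmark data, in this package's composed naming. They span five
#' kinematic channels, which define the five missing-feature robustness
#' scenarios.
#'
#' @return Character vector of nine composed feature names.
#' @export
reference_selected_subset <- function() {
  c("rt_av.mean",
    "lt_av.mean",
    "lt_av.skewness",
    "lf_av.mean",
    "lf_av.kurtosis",
    "lf_av.skewness",
    "ls_v.shape_factor",
    "rt_v.peak_to_peak",
    "lt_av.root_variance_frequency")
}
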