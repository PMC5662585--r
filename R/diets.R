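#' Experimental diet composition constants
#'
#' Printed nutritional characteristics of the four experimental diets
#' (as-is basis): a standard corn-soybean low-fiber finishing diet and a
#' high-fiber diet with 20% corn distillers dried grains with solubles
#' (DDGS), each formulated separately for the commercial and the
#' RFI-selection lines at a constant SID lysine to net energy ratio. The
#' two fiber levels have near-identical net energy, so the high-fiber diet
#' mainly raises the heat increment of feeding, not the energy supply.
#'
#' @return data frame with one row per diet: `diet`, `line_group`,
#'   `fiber`, `ddgs_pct`, `ne_kcal_kg`, `me_kcal_kg`, `ne_me_ratio`,
#'   `crude_protein_pct`, `adf_pct`, `ndf_pct`.
#' @examples
#' d <- diet_table()
#' round(d$ne_kcal_kg[1] / d$me_kcal_kg[1], 2)  # 0.77
#' @export
diet_table <- function() {
  d <- data.frame(
    diet = c("low_fiber_commercial", "high_fiber_commercial",
             "low_fiber_rfi", "high_fiber_rfi"),
    line_group = c("commercial", "commercial", "rfi", "rfi"),
    fiber = c("low", "high", "low", "high"),
    ddgs_pct = c(0, 20, 0, 20),
    ne_kcal_kg = c(2590, 2534, 2604, 2603),
    me_kcal_kg = c(3358, 3372, 3358, 3447),
    crude_protein_pct = c(12.3, 15.6, 11.3, 14.9),
    adf_pct = c(3.04, 5.79, 2.98, 5.81),
    ndf_pct = c(8.68, 13.53, 8.70, 13.81))
  d$ne_me_ratio <- d$ne_kcal_kg / d$me_kcal_kg
  d
}
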