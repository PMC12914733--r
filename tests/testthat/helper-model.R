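# shared fixtures: all built in code at test time

default_p <- cd4kinetics::default_parameters()

mod_static <- cd4kinetics::default_modulations("STATIC")
mod_age <- cd4kinetics::default_modulations("AGE")
mod_fb <- cd4kinetics::default_modulations("AGE_PLUS_FEEDBACK")

# a reproducible random positive state on physiological scales
random_state <- function(seed, scale = 1e8) {
  set.seed(seed)
  cd4kinetics::state_vector(stats::runif(24, 0, scale))
}

# independently hand-assembled 20x20 peripheral rate matrix (blood RTE
# inflow as source b), written term by term from the trafficking topology;
# deliberately NOT derived from the package's flux inventory
oracle_peripheral_matrix <- function(v, lamA) {
  lab <- c("RTE_BL", "RTE_LT", "N_BL", "N_LT", "N_GIT", "N_LUNG",
           "A_BL", "A_LT", "CM_BL", "CM_LT", "CM_GIT", "CM_LUNG",
           "EM_BL", "EM_LT", "EM_GIT", "EM_LUNG",
           "EFF_BL", "EFF_LT", "EFF_GIT", "EFF_LUNG")
  A <- matrix(0, 20, 20, dimnames = list(lab, lab))
  `add` <- function(i, j, x) A[i, j] <<- A[i, j] + x
  add("RTE_BL", "RTE_BL", -(v[["muRTE4"]] + v[["omRTE4bl_lt"]]))
  add("RTE_LT", "RTE_BL", v[["omRTE4bl_lt"]])
  add("RTE_LT", "RTE_LT", -(v[["muRTE4"]] + v[["phiRTE4"]]))
  add("N_LT", "RTE_LT", v[["phiRTE4"]])
  add("N_BL", "N_BL", v[["lamN4"]] - v[["muN4"]] - v[["omN4bl_lt"]] -
        v[["omN4bl_git"]] - v[["omN4bl_lung"]] - v[["omN4bl_tis"]])
  add("N_BL", "N_LT", v[["omN4lt_bl"]])
  add("N_BL", "N_GIT", v[["omN4git_bl"]])
  add("N_BL", "N_LUNG", v[["omN4lung_bl"]])
  add("N_LT", "N_BL", v[["omN4bl_lt"]])
  add("N_LT", "N_LT", v[["lamN4"]] - v[["muN4"]] - v[["phiN4"]] -
        v[["omN4lt_bl"]])
  add("N_GIT", "N_BL", v[["omN4bl_git"]])
  add("N_GIT", "N_GIT", -(v[["muN4"]] + v[["omN4git_bl"]]))
  add("N_LUNG", "N_BL", v[["omN4bl_lung"]])
  add("N_LUNG", "N_LUNG", -(v[["muN4"]] + v[["omN4lung_bl"]]))
  add("A_LT", "N_LT", v[["phiN4"]])
  add("A_BL", "A_BL", lamA - v[["muA4"]] - v[["phiA4"]] -
        v[["omA4bl_lt"]] - v[["omA4bl_tis"]])
  add("A_BL", "A_LT", v[["omA4lt_bl"]])
  add("A_LT", "A_BL", v[["omA4bl_lt"]])
  add("A_LT", "A_LT", lamA - v[["muA4"]] - v[["phiA4"]] - v[["omA4lt_bl"]])
  f4 <- v[["f4"]]
  add("CM_BL", "A_BL", f4 * v[["phiA4"]])
  add("CM_LT", "A_LT", f4 * v[["phiA4"]])
  add("EFF_BL", "A_BL", (1 - f4) * v[["phiA4"]])
  add("EFF_LT", "A_LT", (1 - f4) * v[["phiA4"]])
  dCM <- v[["lamCM4"]] - v[["muCM4"]] - v[["phiCM4"]]
  add("CM_BL", "CM_BL", dCM - v[["omCM4bl_lt"]] - v[["omCM4bl_git"]] -
        v[["omCM4bl_lung"]] - v[["omCM4bl_tis"]])
  add("CM_BL", "CM_LT", v[["omCM4lt_bl"]])
  add("CM_BL", "CM_GIT", v[["omCM4git_bl"]])
  add("CM_BL", "CM_LUNG", v[["omCM4lung_bl"]])
  add("CM_LT", "CM_BL", v[["omCM4bl_lt"]])
  add("CM_LT", "CM_LT", dCM - v[["omCM4lt_bl"]])
  add("CM_GIT", "CM_BL", v[["omCM4bl_git"]])
  add("CM_GIT", "CM_GIT", dCM - v[["omCM4git_bl"]])
  add("CM_LUNG", "CM_BL", v[["omCM4bl_lung"]])
  add("CM_LUNG", "CM_LUNG", dCM - v[["omCM4lung_bl"]])
  dEM <- v[["lamEM4"]] - v[["muEM4"]] - v[["phiEM4"]]
  add("EM_BL", "CM_BL", v[["phiCM4"]])
  add("EM_LT", "CM_LT", v[["phiCM4"]])
  add("EM_GIT", "CM_GIT", v[["phiCM4"]])
  add("EM_LUNG", "CM_LUNG", v[["phiCM4"]])
  add("EM_BL", "EM_BL", dEM - v[["omEM4bl_git"]] - v[["omEM4bl_lung"]] -
        v[["omEM4bl_tis"]])
  add("EM_BL", "EM_LT", v[["omEM4lt_bl"]])
  add("EM_BL", "EM_GIT", v[["omEM4git_bl"]])
  add("EM_BL", "EM_LUNG", v[["omEM4lung_bl"]])
  add("EM_LT", "EM_LT", dEM - v[["omEM4lt_bl"]])
  add("EM_GIT", "EM_BL", v[["omEM4bl_git"]])
  add("EM_GIT", "EM_GIT", dEM - v[["omEM4git_bl"]])
  add("EM_LUNG", "EM_BL", v[["omEM4bl_lung"]])
  add("EM_LUNG", "EM_LUNG", dEM - v[["omEM4lung_bl"]])
  add("EFF_BL", "EM_BL", v[["phiEM4"]])
  add("EFF_LT", "EM_LT", v[["phiEM4"]])
  add("EFF_GIT", "EM_GIT", v[["phiEM4"]])
  add("EFF_LUNG", "EM_LUNG", v[["phiEM4"]])
  add("EFF_BL", "EFF_BL", -(v[["muEFF4"]] + v[["omEFF4bl_git"]] +
        v[["omEFF4bl_lung"]] + v[["omEFF4bl_tis"]]))
  add("EFF_BL", "EFF_LT", v[["omEFF4lt_bl"]])
  add("EFF_LT", "EFF_LT", -(v[["muEFF4"]] + v[["omEFF4lt_bl"]]))
  add("EFF_GIT", "EFF_BL", v[["omEFF4bl_git"]])
  add("EFF_GIT", "EFF_GIT", -v[["muEFF4"]])
  add("EFF_LUNG", "EFF_BL", v[["omEFF4bl_lung"]])
  add("EFF_LUNG", "EFF_LUNG", -v[["muEFF4"]])
  A
}
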