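# Reported two-group concentration ratios for the seven targeted thiols,
# stored as the printed ratio together with the group it favours.
# control_gm_pmol: unspiked endogenous level used as the control geometric
# mean when simulating cohorts (serum/CSF baseline amounts, pmol).
serum:
  CA:       {fold: 1.04,  higher_in: HV,    control_gm_pmol: 0.05}
  Cys:      {fold: 1.089, higher_in: PCNSL, control_gm_pmol: 244.62}
  Hcy:      {fold: 1.36,  higher_in: PCNSL, control_gm_pmol: 10.56}
  GSH:      {fold: 1.25,  higher_in: PCNSL, control_gm_pmol: 1.63}
  Nac:      {fold: 1.25,  higher_in: PCNSL, control_gm_pmol: 0.96}
  Cys-Gly:  {fold: 1.18,  higher_in: HV,    control_gm_pmol: 40.17}
  gGlu-Cys: {fold: 1.89,  higher_in: PCNSL, control_gm_pmol: 5.56}
csf:
  CA:       {fold: 1.14,  higher_in: HV,    control_gm_pmol: 0.03}
  Cys:      {fold: 1.36,  higher_in: PCNSL, control_gm_pmol: 1.68}
  Hcy:      {fold: 1.17,  higher_in: PCNSL, control_gm_pmol: 0.1}
  GSH:      {fold: 1.58,  higher_in: HV,    control_gm_pmol: 0.34}
  Nac:      {fold: 1.40,  higher_in: HV,    control_gm_pmol: 0.08}
  Cys-Gly:  {fold: 1.02,  higher_in: PCNSL, control_gm_pmol: 7.46}
  gGlu-Cys: {fold: 1.09,  higher_in: PCNSL, control_gm_pmol: 0.22}
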