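# Published benchmark summary statistics for the GAFF/IPolQ-Mod+LJ-Fit
# parameterization and its comparison models. One row per
# (dataset, model, statistic, variant).
# dataset: refitting_dG / refitting_rho / validation1_dG / validation2_relsol /
#          validation3_rho
# variant: full = all systems; subset = iodine compounds excluded
#          (validation2: haloperidol/glycerol outliers excluded)
# units: rmsd and mae in kJ/mol for dG datasets, kg/m3 for rho datasets;
#        slope and pearson dimensionless
dataset,model,statistic,variant,value
refitting_dG,GAFF/RESP,rmsd,full,4.64
refitting_dG,GAFF/IPolQ-Mod,rmsd,full,5.39
refitting_dG,GAFF/IPolQ-Mod,rmsd,subset,5.49
refitting_dG,GAFF/IPolQ-Mod+LJ-Fit,rmsd,full,2.39
refitting_dG,GAFF/IPolQ-Mod+LJ-Fit,rmsd,subset,2.43
refitting_dG,GAFF/RESP,mae,full,3.52
refitting_dG,GAFF/IPolQ-Mod,mae,full,3.93
refitting_dG,GAFF/IPolQ-Mod,mae,subset,4.00
refitting_dG,GAFF/IPolQ-Mod+LJ-Fit,mae,full,1.77
refitting_dG,GAFF/IPolQ-Mod+LJ-Fit,mae,subset,1.79
refitting_dG,GAFF/RESP,slope,full,0.9511
refitting_dG,GAFF/IPolQ-Mod,slope,full,1.0452
refitting_dG,GAFF/IPolQ-Mod+LJ-Fit,slope,full,1.0083
refitting_dG,GAFF/RESP,pearson,full,0.9438
refitting_dG,GAFF/IPolQ-Mod,pearson,full,0.9350
refitting_dG,GAFF/IPolQ-Mod+LJ-Fit,pearson,full,0.9850
refitting_rho,GAFF/RESP,rmsd,full,29.80
refitting_rho,GAFF/IPolQ-Mod,rmsd,full,42.55
refitting_rho,GAFF/IPolQ-Mod,rmsd,subset,43.27
refitting_rho,GAFF/IPolQ-Mod+LJ-Fit,rmsd,full,26.15
refitting_rho,GAFF/IPolQ-Mod+LJ-Fit,rmsd,subset,25.66
refitting_rho,GAFF/RESP,mae,full,22.51
refitting_rho,GAFF/IPolQ-Mod,mae,full,33.78
refitting_rho,GAFF/IPolQ-Mod+LJ-Fit,mae,full,19.20
refitting_rho,GAFF/RESP,slope,full,0.9970
refitting_rho,GAFF/IPolQ-Mod,slope,full,0.9938
refitting_rho,GAFF/IPolQ-Mod+LJ-Fit,slope,full,1.0168
refitting_rho,GAFF/RESP,pearson,full,0.9959
refitting_rho,GAFF/IPolQ-Mod,pearson,full,0.9956
refitting_rho,GAFF/IPolQ-Mod+LJ-Fit,pearson,full,0.9979
validation1_dG,GAFF/RESP,rmsd,full,3.30
validation1_dG,GAFF/IPolQ-Mod,rmsd,full,3.96
validation1_dG,GAFF/IPolQ-Mod,rmsd,subset,4.07
validation1_dG,GAFF/IPolQ-Mod+LJ-Fit,rmsd,full,3.14
validation1_dG,GAFF/IPolQ-Mod+LJ-Fit,rmsd,subset,3.09
validation1_dG,GAFF/RESP,mae,full,2.56
validation1_dG,GAFF/IPolQ-Mod,mae,full,3.14
validation1_dG,GAFF/IPolQ-Mod+LJ-Fit,mae,full,2.55
validation1_dG,GAFF/RESP,slope,full,0.9192
validation1_dG,GAFF/IPolQ-Mod,slope,full,0.9801
validation1_dG,GAFF/IPolQ-Mod+LJ-Fit,slope,full,0.9623
validation1_dG,GAFF/RESP,pearson,full,0.9578
validation1_dG,GAFF/IPolQ-Mod,pearson,full,0.9418
validation1_dG,GAFF/IPolQ-Mod+LJ-Fit,pearson,full,0.9701
validation2_relsol,GAFF/RESP,rmsd,full,6.14
validation2_relsol,GAFF/RESP,rmsd,subset,2.98
validation2_relsol,GAFF/IPolQ-Mod+LJ-Fit,rmsd,full,2.28
validation2_relsol,GAFF/IPolQ-Mod+LJ-Fit,rmsd,subset,2.26
validation2_relsol,GAFF/RESP,mae,full,3.41
validation2_relsol,GAFF/RESP,mae,subset,2.40
validation2_relsol,GAFF/IPolQ-Mod+LJ-Fit,mae,full,1.74
validation2_relsol,GAFF/IPolQ-Mod+LJ-Fit,mae,subset,1.72
validation2_relsol,GAFF/RESP,slope,full,0.5550
validation2_relsol,GAFF/IPolQ-Mod+LJ-Fit,slope,full,1.2512
validation2_relsol,GAFF/RESP,pearson,full,0.2358
validation2_relsol,GAFF/IPolQ-Mod+LJ-Fit,pearson,full,0.8286
validation3_rho,GAFF/RESP,rmsd,full,39.06
validation3_rho,GAFF/IPolQ-Mod,rmsd,full,47.85
validation3_rho,GAFF/IPolQ-Mod,rmsd,subset,49.08
validation3_rho,GAFF/IPolQ-Mod+LJ-Fit,rmsd,full,24.93
validation3_rho,GAFF/IPolQ-Mod+LJ-Fit,rmsd,subset,22.89
validation3_rho,GAFF/RESP,mae,full,23.47
validation3_rho,GAFF/IPolQ-Mod,mae,full,31.71
validation3_rho,GAFF/IPolQ-Mod+LJ-Fit,mae,full,17.84
validation3_rho,GAFF/RESP,slope,full,1.002
validation3_rho,GAFF/IPolQ-Mod,slope,full,0.9977
validation3_rho,GAFF/IPolQ-Mod+LJ-Fit,slope,full,1.0132
validation3_rho,GAFF/RESP,pearson,full,0.9816
validation3_rho,GAFF/IPolQ-Mod,pearson,full,0.9856
validation3_rho,GAFF/IPolQ-Mod+LJ-Fit,pearson,full,0.9954
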