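{
  "a": 15,
  "r_k": 0.3,
  "r_C": 1.2,
  "N_k": 25,
  "k_k": 100,
  "p_detach_u0": 0.1,
  "F_detach_u": 4,
  "p_detach_s0": 0.001,
  "F_detach_s": 4,
  "F_PEF": 0.5,
  "F_CENPE": 50,
  "F_DYN": 50,
  "v_g": 12,
  "F_g": 6,
  "v_s": 14,
  "F_s": 4,
  "p_cat0": 0.058,
  "F_cat": 2.4,
  "p_res0": 0.045,
  "F_res": 2.3,
  "N_MT": 10000,
  "p_sc": 0.1,
  "k_nucl": 9,
  "tau_MT": 60,
  "delta_pole": 2.5,
  "tau_refract": 5,
  "eta": 200,
  "n_C": 46,
  "dt": 0.1,
  "deadline_congression": 1000,
  "deadline_biorientation": 100000,
  "eps_congression": 0.1,
  "mode": "fixed_n",
  "arm_geometry": "disk",
  "interpolar_start": false,
  "cenpe_present": true,
  "scenario": "wt_scattered",
  "seed": 100
}
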