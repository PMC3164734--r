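{
  "brazil-2002-males": {
    "label": "Brazil 2002 males", "method": "fitted", "exponent": 9,
    "K": [60.2, 7.1], "theta": [17.8, 2.4], "a": [0.189, 0.023],
    "t_m": [46, null], "d0": [0.0053, 0.0015], "t_c": [11.7, 0.6],
    "chi2_origin": 0.94, "chi2_conv": 1.076, "dof": 11, "p": ">0.999"
  },
  "brazil-2002-females": {
    "label": "Brazil 2002 females", "method": "fitted", "exponent": 9,
    "K": [15.9, 6.4], "theta": [11.3, 4.8], "a": [0.165, 0.070],
    "t_m": [47, null], "d0": [-0.001, 0.002], "t_c": [10.7, 2.0],
    "chi2_origin": 0.12, "chi2_conv": 0.495, "dof": 11, "p": ">0.999"
  },
  "sri-lanka-1999-males": {
    "label": "Sri Lanka 1999 males", "method": "fitted", "exponent": 9,
    "K": [737, 108], "theta": [13.9, 3.3], "a": [0.093, 0.016],
    "t_m": [42.2, 0.6], "d0": [0, null], "t_c": [12.2, 0.8],
    "chi2_origin": 148.3, "chi2_conv": 25.08, "dof": 10, "p": "0.005"
  },
  "usa-2001-males": {
    "label": "USA 2001 males", "method": "fitted", "exponent": 9,
    "K": [287, 17], "theta": [8.20, 0.76], "a": [0.0817, 0.0054],
    "t_m": [46.30, 0.25], "d0": [0.00416, 0.00089], "t_c": [12.0, 0.4],
    "chi2_origin": 6.76, "chi2_conv": 21.37, "dof": 68, "p": ">0.999"
  },
  "usa-2001-females": {
    "label": "USA 2001 females", "method": "fitted", "exponent": 9,
    "K": [15.5, 3.7], "theta": [28.6, 6.1], "a": [0.332, 0.082],
    "t_m": [47, null], "d0": [0, null], "t_c": [11.5, 1.1],
    "chi2_origin": 2.11, "chi2_conv": 32.06, "dof": 71, "p": ">0.999"
  },
  "usa-2001-both": {
    "label": "USA 2001 both genders", "method": "fitted", "exponent": 9,
    "K": [94.3, 7.9], "theta": [15.2, 1.6], "a": [0.147, 0.013],
    "t_m": [47.49, 0.44], "d0": [0.00195, 0.00078], "t_c": [12.2, 0.5],
    "chi2_origin": 2.10, "chi2_conv": 10.42, "dof": 68, "p": ">0.999"
  },
  "usa-2002-males": {
    "label": "USA 2002 males", "method": "fitted", "exponent": 9,
    "K": [271, 18], "theta": [9.19, 0.94], "a": [0.0890, 0.0064],
    "t_m": [46.56, 0.29], "d0": [0.00496, 0.00095], "t_c": [12.2, 0.4],
    "chi2_origin": 8.17, "chi2_conv": 23.60, "dof": 68, "p": ">0.999"
  },
  "usa-2002-females": {
    "label": "USA 2002 females", "method": "fitted", "exponent": 9,
    "K": [18.1, 4.3], "theta": [30.3, 6.9], "a": [0.292, 0.070],
    "t_m": [47, null], "d0": [0, null], "t_c": [12.1, 1.1],
    "chi2_origin": 2.30, "chi2_conv": 32.69, "dof": 69, "p": ">0.999"
  },
  "usa-2002-both": {
    "label": "USA 2002 both genders", "method": "fitted", "exponent": 9,
    "K": [91.4, 8.9], "theta": [16.8, 2.0], "a": [0.155, 0.016],
    "t_m": [47.69, 0.53], "d0": [0.00247, 0.00088], "t_c": [12.4, 0.6],
    "chi2_origin": 2.80, "chi2_conv": 13.47, "dof": 68, "p": ">0.999"
  },
  "usa-2003-both": {
    "label": "USA 2003 both genders", "method": "extrapolated", "exponent": 9,
    "K": [88.4, 9.6], "theta": [18.4, 2.4], "a": [0.163, 0.019],
    "t_m": [47.9, 0.6], "d0": [0.003, 0.001], "t_c": [12.6, 0.6],
    "chi2_origin": null, "chi2_conv": 14.54, "dof": 8, "p": "0.069"
  }
}
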