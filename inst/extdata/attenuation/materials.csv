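name,formula,density_g_cm3
water,H2O,0.997
olive_oil,C57H104O6,0.911
nitromethane,CH3NO2,1.137
acetone,C3H6O,0.784
methanol,CH4O,0.792
ethylenediamine,C2H8N2,0.899
aluminium,Al,2.699
nitrobenzene,C6H5NO2,1.204
iodine,I,4.933
beryllium,Be,1.848
tungsten,W,19.30
air,Air,0.0012041
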