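item,series,conc_cps_per_well,run,positive_wells,n_wells
BP,1,15.00,1,5,5
BP,1,15.00,2,5,5
BP,1,15.00,3,5,5
BP,1,15.00,4,5,5
BP,1,15.00,5,5,5
BP,1,7.50,1,4,5
BP,1,7.50,2,5,5
BP,1,7.50,3,5,5
BP,1,7.50,4,4,5
BP,1,7.50,5,4,5
BP,1,3.75,1,5,5
BP,1,3.75,2,4,5
BP,1,3.75,3,4,5
BP,1,3.75,4,3,5
BP,1,3.75,5,3,5
BP,1,1.88,1,2,5
BP,1,1.88,2,3,5
BP,1,1.88,3,3,5
BP,1,1.88,4,2,5
BP,1,1.88,5,3,5
BP,1,0.94,1,2,5
BP,1,0.94,2,3,5
BP,1,0.94,3,1,5
BP,1,0.94,4,2,5
BP,1,0.94,5,3,5
BP,2,12.50,1,5,5
BP,2,12.50,2,5,5
BP,2,12.50,3,5,5
BP,2,12.50,4,5,5
BP,2,12.50,5,5,5
BP,2,6.25,1,4,5
BP,2,6.25,2,5,5
BP,2,6.25,3,5,5
BP,2,6.25,4,5,5
BP,2,6.25,5,5,5
BP,2,3.13,1,5,5
BP,2,3.13,2,5,5
BP,2,3.13,3,5,5
BP,2,3.13,4,5,5
BP,2,3.13,5,3,5
BP,2,1.56,1,2,5
BP,2,1.56,2,3,5
BP,2,1.56,3,3,5
BP,2,1.56,4,2,5
BP,2,1.56,5,4,5
BP,2,0.78,1,2,5
BP,2,0.78,2,1,5
BP,2,0.78,3,2,5
BP,2,0.78,4,3,5
BP,2,0.78,5,3,5
BP,3,10.00,1,5,5
BP,3,10.00,2,5,5
BP,3,10.00,3,5,5
BP,3,10.00,4,5,5
BP,3,10.00,5,5,5
BP,3,5.00,1,5,5
BP,3,5.00,2,5,5
BP,3,5.00,3,5,5
BP,3,5.00,4,5,5
BP,3,5.00,5,5,5
BP,3,2.50,1,4,5
BP,3,2.50,2,2,5
BP,3,2.50,3,3,5
BP,3,2.50,4,5,5
BP,3,2.50,5,4,5
BP,3,1.25,1,2,5
BP,3,1.25,2,2,5
BP,3,1.25,3,2,5
BP,3,1.25,4,2,5
BP,3,1.25,5,0,5
BP,3,0.63,1,3,5
BP,3,0.63,2,1,5
BP,3,0.63,3,3,5
BP,3,0.63,4,1,5
BP,3,0.63,5,2,5
MP,1,15.00,1,5,5
MP,1,15.00,2,5,5
MP,1,15.00,3,5,5
MP,1,15.00,4,5,5
MP,1,15.00,5,5,5
MP,1,7.50,1,5,5
MP,1,7.50,2,5,5
MP,1,7.50,3,5,5
MP,1,7.50,4,5,5
MP,1,7.50,5,5,5
MP,1,3.75,1,4,5
MP,1,3.75,2,4,5
MP,1,3.75,3,4,5
MP,1,3.75,4,3,5
MP,1,3.75,5,5,5
MP,1,1.88,1,2,5
MP,1,1.88,2,3,5
MP,1,1.88,3,4,5
MP,1,1.88,4,3,5
MP,1,1.88,5,3,5
MP,1,0.94,1,2,5
MP,1,0.94,2,2,5
MP,1,0.94,3,3,5
MP,1,0.94,4,2,5
MP,1,0.94,5,1,5
MP,2,12.50,1,5,5
MP,2,12.50,2,5,5
MP,2,12.50,3,5,5
MP,2,12.50,4,5,5
MP,2,12.50,5,5,5
MP,2,6.25,1,4,5
MP,2,6.25,2,5,5
MP,2,6.25,3,5,5
MP,2,6.25,4,5,5
MP,2,6.25,5,5,5
MP,2,3.13,1,3,5
MP,2,3.13,2,4,5
MP,2,3.13,3,4,5
MP,2,3.13,4,3,5
MP,2,3.13,5,3,5
MP,2,1.56,1,2,5
MP,2,1.56,2,4,5
MP,2,1.56,3,3,5
MP,2,1.56,4,2,5
MP,2,1.56,5,3,5
MP,2,0.78,1,2,5
MP,2,0.78,2,1,5
MP,2,0.78,3,1,5
MP,2,0.78,4,1,5
MP,2,0.78,5,2,5
MP,3,10.00,1,4,5
MP,3,10.00,2,5,5
MP,3,10.00,3,5,5
MP,3,10.00,4,5,5
MP,3,10.00,5,5,5
MP,3,5.00,1,4,5
MP,3,5.00,2,5,5
MP,3,5.00,3,4,5
MP,3,5.00,4,4,5
MP,3,5.00,5,5,5
MP,3,2.50,1,4,5
MP,3,2.50,2,4,5
MP,3,2.50,3,4,5
MP,3,2.50,4,2,5
MP,3,2.50,5,4,5
MP,3,1.25,1,2,5
MP,3,1.25,2,5,5
MP,3,1.25,3,3,5
MP,3,1.25,4,2,5
MP,3,1.25,5,3,5
MP,3,0.63,1,2,5
MP,3,0.63,2,2,5
MP,3,0.63,3,2,5
MP,3,0.63,4,2,5
MP,3,0.63,5,1,5
CP,1,15.00,1,5,5
CP,1,15.00,2,5,5
CP,1,15.00,3,5,5
CP,1,15.00,4,5,5
CP,1,15.00,5,5,5
CP,1,7.50,1,3,5
CP,1,7.50,2,4,5
CP,1,7.50,3,4,5
CP,1,7.50,4,5,5
CP,1,7.50,5,3,5
CP,1,3.75,1,3,5
CP,1,3.75,2,4,5
CP,1,3.75,3,4,5
CP,1,3.75,4,4,5
CP,1,3.75,5,5,5
CP,1,1.88,1,1,5
CP,1,1.88,2,3,5
CP,1,1.88,3,2,5
CP,1,1.88,4,2,5
CP,1,1.88,5,3,5
CP,1,0.94,1,1,5
CP,1,0.94,2,2,5
CP,1,0.94,3,0,5
CP,1,0.94,4,2,5
CP,1,0.94,5,0,5
CP,2,12.50,1,5,5
CP,2,12.50,2,5,5
CP,2,12.50,3,5,5
CP,2,12.50,4,5,5
CP,2,12.50,5,5,5
CP,2,6.25,1,4,5
CP,2,6.25,2,2,5
CP,2,6.25,3,3,5
CP,2,6.25,4,4,5
CP,2,6.25,5,3,5
CP,2,3.13,1,2,5
CP,2,3.13,2,5,5
CP,2,3.13,3,0,5
CP,2,3.13,4,3,5
CP,2,3.13,5,3,5
CP,2,1.56,1,2,5
CP,2,1.56,2,0,5
CP,2,1.56,3,2,5
CP,2,1.56,4,1,5
CP,2,1.56,5,1,5
CP,2,0.78,1,0,5
CP,2,0.78,2,1,5
CP,2,0.78,3,0,5
CP,2,0.78,4,0,5
CP,2,0.78,5,3,5
CP,3,10.00,1,5,5
CP,3,10.00,2,5,5
CP,3,10.00,3,4,5
CP,3,10.00,4,5,5
CP,3,10.00,5,4,5
CP,3,5.00,1,3,5
CP,3,5.00,2,4,5
CP,3,5.00,3,4,5
CP,3,5.00,4,4,5
CP,3,5.00,5,3,5
CP,3,2.50,1,3,5
CP,3,2.50,2,3,5
CP,3,2.50,3,2,5
CP,3,2.50,4,3,5
CP,3,2.50,5,3,5
CP,3,1.25,1,1,5
CP,3,1.25,2,1,5
CP,3,1.25,3,1,5
CP,3,1.25,4,2,5
CP,3,1.25,5,1,5
CP,3,0.63,1,1,5
CP,3,0.63,2,1,5
CP,3,0.63,3,1,5
CP,3,0.63,4,2,5
CP,3,0.63,5,0,5
LP,1,15.00,1,5,5
LP,1,15.00,2,5,5
LP,1,15.00,3,5,5
LP,1,15.00,4,5,5
LP,1,15.00,5,5,5
LP,1,7.50,1,5,5
LP,1,7.50,2,5,5
LP,1,7.50,3,5,5
LP,1,7.50,4,5,5
LP,1,7.50,5,5,5
LP,1,3.75,1,5,5
LP,1,3.75,2,4,5
LP,1,3.75,3,4,5
LP,1,3.75,4,5,5
LP,1,3.75,5,4,5
LP,1,1.88,1,2,5
LP,1,1.88,2,3,5
LP,1,1.88,3,3,5
LP,1,1.88,4,1,5
LP,1,1.88,5,1,5
LP,1,0.94,1,1,5
LP,1,0.94,2,3,5
LP,1,0.94,3,1,5
LP,1,0.94,4,2,5
LP,1,0.94,5,1,5
LP,2,12.50,1,5,5
LP,2,12.50,2,5,5
LP,2,12.50,3,5,5
LP,2,12.50,4,5,5
LP,2,12.50,5,5,5
LP,2,6.25,1,3,5
LP,2,6.25,2,5,5
LP,2,6.25,3,5,5
LP,2,6.25,4,5,5
LP,2,6.25,5,5,5
LP,2,3.13,1,4,5
LP,2,3.13,2,3,5
LP,2,3.13,3,4,5
LP,2,3.13,4,5,5
LP,2,3.13,5,3,5
LP,2,1.56,1,4,5
LP,2,1.56,2,3,5
LP,2,1.56,3,2,5
LP,2,1.56,4,2,5
LP,2,1.56,5,2,5
LP,2,0.78,1,1,5
LP,2,0.78,2,2,5
LP,2,0.78,3,2,5
LP,2,0.78,4,2,5
LP,2,0.78,5,2,5
LP,3,10.00,1,5,5
LP,3,10.00,2,5,5
LP,3,10.00,3,5,5
LP,3,10.00,4,5,5
LP,3,10.00,5,5,5
LP,3,5.00,1,3,5
LP,3,5.00,2,3,5
LP,3,5.00,3,5,5
LP,3,5.00,4,5,5
LP,3,5.00,5,5,5
LP,3,2.50,1,3,5
LP,3,2.50,2,1,5
LP,3,2.50,3,2,5
LP,3,2.50,4,1,5
LP,3,2.50,5,4,5
LP,3,1.25,1,3,5
LP,3,1.25,2,1,5
LP,3,1.25,3,2,5
LP,3,1.25,4,1,5
LP,3,1.25,5,4,5
LP,3,0.63,1,1,5
LP,3,0.63,2,2,5
LP,3,0.63,3,2,5
LP,3,0.63,4,1,5
LP,3,0.63,5,2,5
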