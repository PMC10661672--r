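survey,sex,band,source,year,prevalence,ci_low,ci_high
ctums,male,15+,model,2012,18.3,,
ctums,male,15+,model,2017,16.1,,
ctums,male,15+,model,2020,14.8,,
ctums,male,15+,survey,2012,17.8,17.4,18.2
ctums,male,15+,survey,2017,15.8,13.7,18.3
ctums,male,15+,survey,2020,11.7,10.4,13.1
ctums,male,15-24,model,2012,16.0,,
ctums,male,15-24,model,2017,13.5,,
ctums,male,15-24,model,2020,12.5,,
ctums,male,15-24,survey,2012,15.7,15.3,16.2
ctums,male,15-24,survey,2017,12.3,10.4,14.4
ctums,male,15-24,survey,2020,7.3,5.8,9.2
ctums,male,25-44,model,2012,24.1,,
ctums,male,25-44,model,2017,21.3,,
ctums,male,25-44,model,2020,19.1,,
ctums,male,25-44,survey,2012,22.9,22.0,23.8
ctums,male,25-44,survey,2017,17.7,13.5,22.9
ctums,male,25-44,survey,2020,12.1,9.6,15.3
ctums,male,45-64,model,2012,18.4,,
ctums,male,45-64,model,2017,16.7,,
ctums,male,45-64,model,2020,15.9,,
ctums,male,45-64,survey,2012,18.1,17.4,18.8
ctums,male,45-64,survey,2017,20.1,16.4,24.5
ctums,male,45-64,survey,2020,12.6,10.4,15.2
ctums,male,65+,model,2012,8.2,,
ctums,male,65+,model,2017,7.5,,
ctums,male,65+,model,2020,7.1,,
ctums,male,65+,survey,2012,8.4,7.7,9.1
ctums,male,65+,survey,2017,7.6,4.5,12.8
ctums,male,65+,survey,2020,12.5,10.1,15.5
ctums,female,15+,model,2012,13.7,,
ctums,female,15+,model,2017,11.7,,
ctums,female,15+,model,2020,10.6,,
ctums,female,15+,survey,2012,13.3,13.1,13.6
ctums,female,15+,survey,2017,12.9,11.2,14.8
ctums,female,15+,survey,2020,8.4,7.4,9.6
ctums,female,15-24,model,2012,12.1,,
ctums,female,15-24,model,2017,10.1,,
ctums,female,15-24,model,2020,9.3,,
ctums,female,15-24,survey,2012,11.8,11.4,12.2
ctums,female,15-24,survey,2017,6.4,5.1,7.9
ctums,female,15-24,survey,2020,2.9,1.9,4.2
ctums,female,25-44,model,2012,15.8,,
ctums,female,25-44,model,2017,12.4,,
ctums,female,25-44,model,2020,10.6,,
ctums,female,25-44,survey,2012,15.2,14.6,15.9
ctums,female,25-44,survey,2017,17.5,13.6,22.3
ctums,female,25-44,survey,2020,8.4,6.5,10.8
ctums,female,45-64,model,2012,14.5,,
ctums,female,45-64,model,2017,12.8,,
ctums,female,45-64,model,2020,11.7,,
ctums,female,45-64,survey,2012,14.4,13.9,15.0
ctums,female,45-64,survey,2017,14.1,11.3,17.4
ctums,female,45-64,survey,2020,10.9,8.9,13.2
ctums,female,65+,model,2012,10.0,,
ctums,female,65+,model,2017,9.9,,
ctums,female,65+,model,2020,10.1,,
ctums,female,65+,survey,2012,9.3,8.8,9.8
ctums,female,65+,survey,2017,8.4,5.7,12.2
ctums,female,65+,survey,2020,8.4,6.6,10.7
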