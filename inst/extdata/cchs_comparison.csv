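survey,sex,band,source,year,prevalence,ci_low,ci_high
cchs,male,18+,model,2012,18.8,,
cchs,male,18+,model,2018,15.9,,
cchs,male,18+,model,2020,15.1,,
cchs,male,18+,survey,2012,23.8,22.8,24.8
cchs,male,18+,survey,2018,18.7,17.8,19.6
cchs,male,18+,survey,2020,15.7,14.7,16.7
cchs,male,18-24,model,2012,19.0,,
cchs,male,18-24,model,2018,15.1,,
cchs,male,18-24,model,2020,14.6,,
cchs,male,18-24,survey,2012,27.2,24.0,30.3
cchs,male,18-24,survey,2018,18.5,15.7,21.3
cchs,male,18-24,survey,2020,9.5,6.8,12.2
cchs,male,25-44,model,2012,24.1,,
cchs,male,25-44,model,2018,20.5,,
cchs,male,25-44,model,2020,19.1,,
cchs,male,25-44,survey,2012,27.9,26.0,29.7
cchs,male,25-44,survey,2018,21.4,19.7,23.1
cchs,male,25-44,survey,2020,19.9,17.7,22.0
cchs,male,45-64,model,2012,18.4,,
cchs,male,45-64,model,2018,16.4,,
cchs,male,45-64,model,2020,15.9,,
cchs,male,45-64,survey,2012,25.1,23.3,27.0
cchs,male,45-64,survey,2018,20.7,19.2,22.3
cchs,male,45-64,survey,2020,17.6,15.9,19.4
cchs,male,65+,model,2012,8.2,,
cchs,male,65+,model,2018,7.3,,
cchs,male,65+,model,2020,7.1,,
cchs,male,65+,survey,2012,9.9,8.8,11.1
cchs,male,65+,survey,2018,10.6,9.3,11.9
cchs,male,65+,survey,2020,9.2,8.1,10.3
cchs,female,18+,model,2012,13.9,,
cchs,female,18+,model,2018,11.4,,
cchs,female,18+,model,2020,10.8,,
cchs,female,18+,survey,2012,17.6,16.8,18.5
cchs,female,18+,survey,2018,13.1,12.4,13.8
cchs,female,18+,survey,2020,10.3,9.5,11.0
cchs,female,18-24,model,2012,13.7,,
cchs,female,18-24,model,2018,10.6,,
cchs,female,18-24,model,2020,10.2,,
cchs,female,18-24,survey,2012,18.0,15.2,20.9
cchs,female,18-24,survey,2018,10.2,7.8,12.7
cchs,female,18-24,survey,2020,3.9,2.3,5.5
cchs,female,25-44,model,2012,15.8,,
cchs,female,25-44,model,2018,11.7,,
cchs,female,25-44,model,2020,10.6,,
cchs,female,25-44,survey,2012,19.9,18.4,21.4
cchs,female,25-44,survey,2018,14.7,13.5,15.9
cchs,female,25-44,survey,2020,11.3,9.9,12.8
cchs,female,45-64,model,2012,14.5,,
cchs,female,45-64,model,2018,12.4,,
cchs,female,45-64,model,2020,11.7,,
cchs,female,45-64,survey,2012,20.1,18.6,21.6
cchs,female,45-64,survey,2018,15.7,14.4,17.0
cchs,female,45-64,survey,2020,13.0,11.6,14.4
cchs,female,65+,model,2012,10.0,,
cchs,female,65+,model,2018,9.9,,
cchs,female,65+,model,2020,10.1,,
cchs,female,65+,survey,2012,8.9,8.0,9.8
cchs,female,65+,survey,2018,8.2,7.2,9.2
cchs,female,65+,survey,2020,7.1,6.3,7.9
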