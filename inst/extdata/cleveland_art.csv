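feature,shap_xgboost,shap_rf,shap_svm,avg
ca,1,2,2,1.666667
thal,3,1,1,1.666667
cp,2,3,3,2.666667
thalach,6,4,7,5.666667
exang,8,6,4,6.000000
sex,5,9,5,6.333333
slope,4,7,8,6.333333
oldpeak,7,5,9,7.000000
restecg,11,11,6,9.333333
age,9,8,12,9.666667
chol,10,10,13,11.000000
trestbps,12,12,11,11.666667
fbs,13,13,10,12.000000
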