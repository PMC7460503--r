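source,model,speed,phase,metric,value
per_class_summary,lstm,0.78,HS,precision,0
per_class_summary,lstm,0.78,FF,precision,89.0
per_class_summary,lstm,0.78,HO,precision,94.6
per_class_summary,lstm,0.78,SW,precision,98.3
per_class_summary,lstm,0.78,HS,recall,0
per_class_summary,lstm,0.78,FF,recall,97.9
per_class_summary,lstm,0.78,HO,recall,93.9
per_class_summary,lstm,0.78,SW,recall,97.2
per_class_summary,lstm,0.78,HS,f1,0
per_class_summary,lstm,0.78,FF,f1,93.3
per_class_summary,lstm,0.78,HO,f1,94.3
per_class_summary,lstm,0.78,SW,f1,97.8
per_class_summary,lstm,1.0,HS,precision,0
per_class_summary,lstm,1.0,FF,precision,90.5
per_class_summary,lstm,1.0,HO,precision,95.6
per_class_summary,lstm,1.0,SW,precision,97.8
per_class_summary,lstm,1.0,HS,recall,0
per_class_summary,lstm,1.0,FF,recall,98.5
per_class_summary,lstm,1.0,HO,recall,93.4
per_class_summary,lstm,1.0,SW,recall,97.8
per_class_summary,lstm,1.0,HS,f1,0
per_class_summary,lstm,1.0,FF,f1,94.3
per_class_summary,lstm,1.0,HO,f1,94.5
per_class_summary,lstm,1.0,SW,f1,97.8
per_class_summary,lstm,1.25,HS,precision,0
per_class_summary,lstm,1.25,FF,precision,91.8
per_class_summary,lstm,1.25,HO,precision,95.2
per_class_summary,lstm,1.25,SW,precision,96.4
per_class_summary,lstm,1.25,HS,recall,0
per_class_summary,lstm,1.25,FF,recall,97.6
per_class_summary,lstm,1.25,HO,recall,92.9
per_class_summary,lstm,1.25,SW,recall,98.0
per_class_summary,lstm,1.25,HS,f1,0
per_class_summary,lstm,1.25,FF,f1,94.6
per_class_summary,lstm,1.25,HO,f1,94.0
per_class_summary,lstm,1.25,SW,f1,97.2
per_class_summary,lstm_cnn,0.78,HS,precision,0
per_class_summary,lstm_cnn,0.78,FF,precision,91.3
per_class_summary,lstm_cnn,0.78,HO,precision,93.8
per_class_summary,lstm_cnn,0.78,SW,precision,98.5
per_class_summary,lstm_cnn,0.78,HS,recall,0
per_class_summary,lstm_cnn,0.78,FF,recall,98.2
per_class_summary,lstm_cnn,0.78,HO,recall,96.3
per_class_summary,lstm_cnn,0.78,SW,recall,97.4
per_class_summary,lstm_cnn,0.78,HS,f1,0
per_class_summary,lstm_cnn,0.78,FF,f1,94.6
per_class_summary,lstm_cnn,0.78,HO,f1,95.1
per_class_summary,lstm_cnn,0.78,SW,f1,98.0
per_class_summary,lstm_cnn,1.0,HS,precision,0
per_class_summary,lstm_cnn,1.0,FF,precision,92.8
per_class_summary,lstm_cnn,1.0,HO,precision,97.6
per_class_summary,lstm_cnn,1.0,SW,precision,97.9
per_class_summary,lstm_cnn,1.0,HS,recall,0
per_class_summary,lstm_cnn,1.0,FF,recall,99.0
per_class_summary,lstm_cnn,1.0,HO,recall,97.3
per_class_summary,lstm_cnn,1.0,SW,recall,98.9
per_class_summary,lstm_cnn,1.0,HS,f1,0
per_class_summary,lstm_cnn,1.0,FF,f1,95.8
per_class_summary,lstm_cnn,1.0,HO,f1,97.4
per_class_summary,lstm_cnn,1.0,SW,f1,98.4
per_class_summary,lstm_cnn,1.25,HS,precision,0
per_class_summary,lstm_cnn,1.25,FF,precision,91.9
per_class_summary,lstm_cnn,1.25,HO,precision,97.2
per_class_summary,lstm_cnn,1.25,SW,precision,98.1
per_class_summary,lstm_cnn,1.25,HS,recall,0
per_class_summary,lstm_cnn,1.25,FF,recall,99.2
per_class_summary,lstm_cnn,1.25,HO,recall,95.7
per_class_summary,lstm_cnn,1.25,SW,recall,98.7
per_class_summary,lstm_cnn,1.25,HS,f1,0
per_class_summary,lstm_cnn,1.25,FF,f1,95.4
per_class_summary,lstm_cnn,1.25,HO,f1,96.4
per_class_summary,lstm_cnn,1.25,SW,f1,98.4
per_class_summary,fmsnet,0.78,HS,precision,73.8
per_class_summary,fmsnet,0.78,FF,precision,94.5
per_class_summary,fmsnet,0.78,HO,precision,98.2
per_class_summary,fmsnet,0.78,SW,precision,99.2
per_class_summary,fmsnet,0.78,HS,recall,56.0
per_class_summary,fmsnet,0.78,FF,recall,98.3
per_class_summary,fmsnet,0.78,HO,recall,97.0
per_class_summary,fmsnet,0.78,SW,recall,98.4
per_class_summary,fmsnet,0.78,HS,f1,63.7
per_class_summary,fmsnet,0.78,FF,f1,96.4
per_class_summary,fmsnet,0.78,HO,f1,97.6
per_class_summary,fmsnet,0.78,SW,f1,98.8
per_class_summary,fmsnet,1.0,HS,precision,82.3
per_class_summary,fmsnet,1.0,FF,precision,96.8
per_class_summary,fmsnet,1.0,HO,precision,98.5
per_class_summary,fmsnet,1.0,SW,precision,99.1
per_class_summary,fmsnet,1.0,HS,recall,71.6
per_class_summary,fmsnet,1.0,FF,recall,98.4
per_class_summary,fmsnet,1.0,HO,recall,97.9
per_class_summary,fmsnet,1.0,SW,recall,98.9
per_class_summary,fmsnet,1.0,HS,f1,76.6
per_class_summary,fmsnet,1.0,FF,f1,97.6
per_class_summary,fmsnet,1.0,HO,f1,98.2
per_class_summary,fmsnet,1.0,SW,f1,99.0
per_class_summary,fmsnet,1.25,HS,precision,82.9
per_class_summary,fmsnet,1.25,FF,precision,95.6
per_class_summary,fmsnet,1.25,HO,precision,97.4
per_class_summary,fmsnet,1.25,SW,precision,97.8
per_class_summary,fmsnet,1.25,HS,recall,41.0
per_class_summary,fmsnet,1.25,FF,recall,98.5
per_class_summary,fmsnet,1.25,HO,recall,97.4
per_class_summary,fmsnet,1.25,SW,recall,98.3
per_class_summary,fmsnet,1.25,HS,f1,54.9
per_class_summary,fmsnet,1.25,FF,f1,97.1
per_class_summary,fmsnet,1.25,HO,f1,97.4
per_class_summary,fmsnet,1.25,SW,f1,98.1
overall_summary,lstm,0.78,,accuracy,94.2
overall_summary,lstm,0.78,,macro_f1,71.3
overall_summary,lstm,0.78,,macro_auc,0.89
overall_summary,lstm_cnn,0.78,,accuracy,95.1
overall_summary,lstm_cnn,0.78,,macro_f1,71.9
overall_summary,lstm_cnn,0.78,,macro_auc,0.89
overall_summary,fmsnet,0.78,,accuracy,96.7
overall_summary,fmsnet,0.78,,macro_f1,88.9
overall_summary,fmsnet,0.78,,macro_auc,0.99
overall_summary,no_skip,0.78,,accuracy,96.5
overall_summary,no_skip,0.78,,macro_f1,88.0
overall_summary,no_skip,0.78,,macro_auc,0.99
overall_summary,lstm,1.0,,accuracy,94.7
overall_summary,lstm,1.0,,macro_f1,71.6
overall_summary,lstm,1.0,,macro_auc,0.92
overall_summary,lstm_cnn,1.0,,accuracy,96.0
overall_summary,lstm_cnn,1.0,,macro_f1,72.9
overall_summary,lstm_cnn,1.0,,macro_auc,0.91
overall_summary,fmsnet,1.0,,accuracy,97.8
overall_summary,fmsnet,1.0,,macro_f1,92.8
overall_summary,fmsnet,1.0,,macro_auc,1.0
overall_summary,no_skip,1.0,,accuracy,97.2
overall_summary,no_skip,1.0,,macro_f1,91.7
overall_summary,no_skip,1.0,,macro_auc,0.99
overall_summary,lstm,1.25,,accuracy,94.4
overall_summary,lstm,1.25,,macro_f1,71.4
overall_summary,lstm,1.25,,macro_auc,0.93
overall_summary,lstm_cnn,1.25,,accuracy,95.7
overall_summary,lstm_cnn,1.25,,macro_f1,72.5
overall_summary,lstm_cnn,1.25,,macro_auc,0.91
overall_summary,fmsnet,1.25,,accuracy,96.8
overall_summary,fmsnet,1.25,,macro_f1,86.9
overall_summary,fmsnet,1.25,,macro_auc,0.99
overall_summary,no_skip,1.25,,accuracy,96.6
overall_summary,no_skip,1.25,,macro_f1,85.9
overall_summary,no_skip,1.25,,macro_auc,0.99
reported_average,fmsnet,,HS,f1_mean,65.1
reported_average,fmsnet,,,macro_f1_mean,89.5
reported_average,lstm_cnn,,,macro_f1_mean,72.4
reported_average,lstm,,,macro_f1_mean,71.4
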